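#include <Rcpp.h>
using namespace Rcpp;

// Sliding ungapped placement of each read against a set of reference
// sequences.  Every offset of every reference is scored by Hamming
// mismatches (with early exit once the running count exceeds the best seen);
// ties keep the first reference/offset encountered, so plain amplicon
// references listed before indel-applied ones win ties.
// [[Rcpp::export]]
DataFrame cpp_best_placement(CharacterVector reads, CharacterVector refs) {
  int nr = reads.size(), nf = refs.size();
  std::vector<std::string> rf(nf);
  for (int j = 0; j < nf; ++j) rf[j] = as<std::string>(refs[j]);
  IntegerVector best_ref(nr), best_off(nr), best_mm(nr);
  for (int i = 0; i < nr; ++i) {
    std::string rd = as<std::string>(reads[i]);
    int lr = rd.size();
    int bref = NA_INTEGER, boff = NA_INTEGER, bmm = lr + 1;
    // prefix pre-filter: a placement whose first 16 bases already hold >8
    // mismatches cannot be a sub-20% alignment of a 32+ bp read, so the
    // full scan is skipped; random placements average ~12/16 mismatches
    int plen = (lr >= 32) ? 16 : 0;
    for (int j = 0; j < nf && bmm > 0; ++j) {
      int lf = rf[j].size();
      if (lf < lr) continue;
      const char* f = rf[j].c_str();
      const char* r = rd.c_str();
      for (int o = 0; o <= lf - lr; ++o) {
        if (plen) {
          int qmm = 0;
          for (int k = 0; k < plen; ++k) qmm += (r[k] != f[o + k]);
          if (qmm > 8) continue;
        }
        int mm = 0;
        for (int k = 0; k < lr; ++k) {
          if (r[k] != f[o + k] && ++mm >= bmm) break;
        }
        if (mm < bmm) { bmm = mm; bref = j + 1; boff = o; }
        if (bmm == 0) break;
      }
    }
    best_ref[i] = bref;
    best_off[i] = boff;
    best_mm[i] = (bmm <= lr) ? bmm : NA_INTEGER;
  }
  return DataFrame::create(_["ref"] = best_ref, _["offset"] = best_off,
                           _["mismatches"] = best_mm);
}

// Build one reference-coordinate string per read pair.  Each mate is placed
// at `off` (0-based, in the coordinates of the reference it aligned to); if
// the mate aligned to an indel-applied reference, dstart/dlen give the
// deleted segment in plain-amplicon coordinates and mate positions at or
// beyond dstart are shifted right by dlen.  A mate spanning the deletion
// junction writes '-' over the deleted positions.  Mate disagreement at an
// overlapping position yields 'N'; uncovered positions stay '.'.
// [[Rcpp::export]]
CharacterVector cpp_paired_aligned(int amp_len,
                                   IntegerVector off1, CharacterVector seq1,
                                   IntegerVector d1start, IntegerVector d1len,
                                   IntegerVector off2, CharacterVector seq2,
                                   IntegerVector d2start, IntegerVector d2len) {
  int n = off1.size();
  CharacterVector out(n);
  std::string buf;
  for (int i = 0; i < n; ++i) {
    buf.assign(amp_len, '.');
    for (int m = 0; m < 2; ++m) {
      int off = (m == 0) ? off1[i] : off2[i];
      if (off == NA_INTEGER) continue;
      std::string sq = as<std::string>((m == 0) ? seq1[i] : seq2[i]);
      int ds = (m == 0) ? d1start[i] : d2start[i];
      int dl = (m == 0) ? d1len[i] : d2len[i];
      bool hasdel = (ds != NA_INTEGER && dl != NA_INTEGER && dl > 0);
      int lr = sq.size();
      for (int k = 0; k < lr; ++k) {
        int q = off + k;                       // position in aligned-ref coords
        int p = (hasdel && q >= ds) ? q + dl : q;  // plain-amplicon coords
        if (p < 0 || p >= amp_len) continue;
        char b = sq[k];
        if (buf[p] == '.') buf[p] = b;
        else if (buf[p] != b) buf[p] = 'N';
      }
      if (hasdel && off < ds && off + lr > ds) {
        for (int p = ds; p < ds + dl && p < amp_len; ++p) {
          if (buf[p] == '.') buf[p] = '-';
          else if (buf[p] != '-') buf[p] = 'N';
        }
      }
    }
    out[i] = buf;
  }
  return out;
}

// Majority-vote consensus per group of aligned strings.  For each group and
// position, the most frequent of A,C,G,T,- wins if its fraction of the
// covering members is >= min_agreement (ties at the threshold kept, first
// symbol in A,C,G,T,- order wins exact ties); otherwise 'N'.  Uncovered
// positions give '.'.
// [[Rcpp::export]]
CharacterVector cpp_group_consensus(CharacterVector aligned,
                                    IntegerVector group, int n_groups,
                                    int len, double min_agreement) {
  static const char syms[5] = {'A', 'C', 'G', 'T', '-'};
  std::vector<int> counts((size_t)n_groups * len * 5, 0);
  int n = aligned.size();
  for (int i = 0; i < n; ++i) {
    int g = group[i] - 1;
    std::string s = as<std::string>(aligned[i]);
    int l = std::min((int)s.size(), len);
    for (int p = 0; p < l; ++p) {
      int col;
      switch (s[p]) {
        case 'A': col = 0; break;
        case 'C': col = 1; break;
        case 'G': col = 2; break;
        case 'T': col = 3; break;
        case '-': col = 4; break;
        default: continue;
      }
      counts[((size_t)g * len + p) * 5 + col]++;
    }
  }
  CharacterVector out(n_groups);
  std::string buf(len, '.');
  for (int g = 0; g < n_groups; ++g) {
    for (int p = 0; p < len; ++p) {
      const int* c = &counts[((size_t)g * len + p) * 5];
      int cov = c[0] + c[1] + c[2] + c[3] + c[4];
      if (cov == 0) { buf[p] = '.'; continue; }
      int best = 0;
      for (int b = 1; b < 5; ++b) if (c[b] > c[best]) best = b;
      buf[p] = (c[best] >= min_agreement * cov - 1e-9) ? syms[best] : 'N';
    }
    out[g] = buf;
  }
  return out;
}

// Substitute n_err[i] distinct random positions of x[i] with a random
// different base.  Randomness comes from R's RNG stream (unif_rand), so
// results are reproducible under set.seed().
// [[Rcpp::export]]
CharacterVector cpp_mutate_bases(CharacterVector x, IntegerVector n_err) {
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  int n = x.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    if (n_err[i] <= 0) { out[i] = x[i]; continue; }
    std::string s = as<std::string>(x[i]);
    int len = s.size(), k = n_err[i];
    std::vector<int> used;
    for (int e = 0; e < k; ++e) {
      int p;
      do {
        p = (int)(unif_rand() * len);
        if (p >= len) p = len - 1;
      } while (std::find(used.begin(), used.end(), p) != used.end());
      used.push_back(p);
      char cur = s[p], nb;
      do {
        nb = bases[(int)(unif_rand() * 4) & 3];
      } while (nb == cur);
      s[p] = nb;
    }
    out[i] = s;
  }
  return out;
}

// Tabulate aligned strings (one per read or consensus record) into
// per-group, per-position counts of the six pileup symbols A,C,G,T,-,N.
// Returns an integer matrix with n_groups*len rows (position fastest) and
// 6 columns.  '.' (uncovered) is not counted.
// [[Rcpp::export]]
IntegerMatrix cpp_pileup_counts(CharacterVector aligned, IntegerVector group,
                                int n_groups, int len) {
  IntegerMatrix counts(n_groups * len, 6);
  int n = aligned.size();
  for (int i = 0; i < n; ++i) {
    int g = group[i] - 1;
    std::string s = as<std::string>(aligned[i]);
    int l = std::min((int)s.size(), len);
    for (int p = 0; p < l; ++p) {
      int col;
      switch (s[p]) {
        case 'A': col = 0; break;
        case 'C': col = 1; break;
        case 'G': col = 2; break;
        case 'T': col = 3; break;
        case '-': col = 4; break;
        case 'N': col = 5; break;
        default: continue;
      }
      counts(g * len + p, col)++;
    }
  }
  return counts;
}
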