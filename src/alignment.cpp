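#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

// Smith-Waterman local alignment, score only, affine gaps.
// A gap of length L costs gap_open + L * gap_extend (opening charge plus a
// per-base extension charge), matching the pairwiseAlignment convention.
static int sw_score_one(const char* a, int na, const char* b, int nb,
                        int match, int mismatch, int gap_open, int gap_extend) {
  if (na == 0 || nb == 0) return 0;
  const int NEG = INT32_MIN / 4;
  std::vector<int> H(nb + 1, 0), F(nb + 1, NEG);
  int best = 0;
  for (int i = 1; i <= na; ++i) {
    int hdiag = 0;  // H[i-1][j-1]
    int e = NEG;
    const char ai = a[i - 1];
    for (int j = 1; j <= nb; ++j) {
      const int hup = H[j];  // H[i-1][j]
      int f = hup + gap_open + gap_extend;
      const int fext = F[j] + gap_extend;
      if (fext > f) f = fext;
      F[j] = f;
      int enew = H[j - 1] + gap_open + gap_extend;  // H[j-1] already row i
      const int eext = e + gap_extend;
      if (eext > enew) enew = eext;
      e = enew;
      int h = hdiag + (ai == b[j - 1] ? match : mismatch);
      if (e > h) h = e;
      if (f > h) h = f;
      if (h < 0) h = 0;
      hdiag = hup;
      H[j] = h;
      if (h > best) best = h;
    }
  }
  return best;
}

// Banded variant: only cells with diagonal j - i in [dlo, dhi] are filled.
// Outside-band H is treated as 0 (a fresh local start at the band edge), so
// the result is a lower bound on the unbanded score with equality whenever
// the optimal path stays inside the band.
static int sw_score_banded(const char* a, int na, const char* b, int nb,
                           int match, int mismatch, int gap_open,
                           int gap_extend, int dlo, int dhi) {
  if (na == 0 || nb == 0) return 0;
  const int NEG = INT32_MIN / 4;
  std::vector<int> H(nb + 1, 0), F(nb + 1, NEG);
  int best = 0;
  for (int i = 1; i <= na; ++i) {
    int jlo = i + dlo;
    int jhi = i + dhi;
    if (jlo < 1) jlo = 1;
    if (jhi > nb) jhi = nb;
    if (jlo > jhi) continue;
    int hdiag = H[jlo - 1];  // previous row, left band edge
    int e = NEG, hleft = NEG;
    const char ai = a[i - 1];
    for (int j = jlo; j <= jhi; ++j) {
      const int hup = H[j];
      int f = hup + gap_open + gap_extend;
      const int fext = F[j] + gap_extend;
      if (fext > f) f = fext;
      F[j] = f;
      int enew = hleft + gap_open + gap_extend;
      const int eext = e + gap_extend;
      if (eext > enew) enew = eext;
      e = enew;
      int h = hdiag + (ai == b[j - 1] ? match : mismatch);
      if (e > h) h = e;
      if (f > h) h = f;
      if (h < 0) h = 0;
      hdiag = hup;
      hleft = h;
      H[j] = h;
      if (h > best) best = h;
    }
  }
  return best;
}

// [[Rcpp::export]]
int sw_score_cpp(std::string query, std::string subject, int match,
                 int mismatch, int gap_open, int gap_extend) {
  return sw_score_one(query.c_str(), (int)query.size(), subject.c_str(),
                      (int)subject.size(), match, mismatch, gap_open,
                      gap_extend);
}

// [[Rcpp::export]]
IntegerVector sw_scores_cpp(std::string query, CharacterVector subjects,
                            int match, int mismatch, int gap_open,
                            int gap_extend) {
  const int n = subjects.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(subjects, i));
    out[i] = sw_score_one(query.c_str(), (int)query.size(), s,
                          (int)LENGTH(STRING_ELT(subjects, i)), match, mismatch,
                          gap_open, gap_extend);
  }
  return out;
}

static inline bool encode_kmer(const char* s, int k, uint32_t& code) {
  uint32_t c = 0;
  for (int i = 0; i < k; ++i) {
    uint32_t v;
    switch (s[i]) {
      case 'A': v = 0; break;
      case 'C': v = 1; break;
      case 'G': v = 2; break;
      case 'T': v = 3; break;
      default: return false;  // skip k-mers containing N etc.
    }
    c = (c << 2) | v;
  }
  code = c;
  return true;
}

// Top-hit search of every read against a reference panel.
// seeded = true restricts alignment to references sharing at least one exact
// k-mer with the read; seeded = false aligns against the full panel.
// band_pad >= 0 with seeded additionally restricts each candidate alignment
// to a diagonal band around its seed k-mer diagonals (seed-and-extend);
// band_pad < 0 runs full Smith-Waterman on every candidate.
// Status per read: 0 = ok, 1 = query shorter than min_query_length,
// 2 = no candidate shares a k-mer (seeded engine only).
// [[Rcpp::export]]
List search_top_hits_cpp(CharacterVector reads, CharacterVector refs,
                         int match, int mismatch, int gap_open, int gap_extend,
                         int k, bool seeded, int min_query_length,
                         int band_pad) {
  const int n_reads = reads.size();
  const int n_refs = refs.size();
  if (k < 3 || k > 15) stop("k must be between 3 and 15");

  // k-mer -> (reference, position) postings
  std::unordered_map<uint32_t, std::vector<std::pair<int, int>>> index;
  if (seeded) {
    index.reserve(1 << 18);
    for (int r = 0; r < n_refs; ++r) {
      const char* s = CHAR(STRING_ELT(refs, r));
      const int ns = LENGTH(STRING_ELT(refs, r));
      for (int p = 0; p + k <= ns; ++p) {
        uint32_t code;
        if (!encode_kmer(s + p, k, code)) continue;
        index[code].push_back(std::make_pair(r, p));
      }
    }
  }

  std::vector<int> read_out, ref_out;
  IntegerVector top_score(n_reads), status(n_reads), n_candidates(n_reads);
  std::vector<int> stamp(n_refs, -1);
  std::vector<int> diag_lo(n_refs, 0), diag_hi(n_refs, 0);
  std::vector<int> cand;
  cand.reserve(n_refs);

  for (int i = 0; i < n_reads; ++i) {
    const char* q = CHAR(STRING_ELT(reads, i));
    const int nq = LENGTH(STRING_ELT(reads, i));
    top_score[i] = NA_INTEGER;
    if (nq < min_query_length) {
      status[i] = 1;
      n_candidates[i] = 0;
      continue;
    }
    cand.clear();
    if (seeded) {
      for (int p = 0; p + k <= nq; ++p) {
        uint32_t code;
        if (!encode_kmer(q + p, k, code)) continue;
        auto it = index.find(code);
        if (it == index.end()) continue;
        for (const std::pair<int, int>& hit : it->second) {
          const int r = hit.first;
          const int d = hit.second - p;  // diagonal j - i of this seed
          if (stamp[r] != i) {
            stamp[r] = i;
            cand.push_back(r);
            diag_lo[r] = d;
            diag_hi[r] = d;
          } else {
            if (d < diag_lo[r]) diag_lo[r] = d;
            if (d > diag_hi[r]) diag_hi[r] = d;
          }
        }
      }
      if (cand.empty()) {
        status[i] = 2;
        n_candidates[i] = 0;
        continue;
      }
    } else {
      for (int r = 0; r < n_refs; ++r) cand.push_back(r);
    }
    n_candidates[i] = (int)cand.size();
    int best = INT32_MIN;
    std::vector<int> best_refs;
    for (int r : cand) {
      const char* s = CHAR(STRING_ELT(refs, r));
      const int ns = LENGTH(STRING_ELT(refs, r));
      int sc;
      if (seeded && band_pad >= 0) {
        sc = sw_score_banded(q, nq, s, ns, match, mismatch, gap_open,
                             gap_extend, diag_lo[r] - band_pad,
                             diag_hi[r] + band_pad);
      } else {
        sc = sw_score_one(q, nq, s, ns, match, mismatch, gap_open, gap_extend);
      }
      if (sc > best) {
        best = sc;
        best_refs.clear();
        best_refs.push_back(r);
      } else if (sc == best) {
        best_refs.push_back(r);
      }
    }
    std::sort(best_refs.begin(), best_refs.end());  // library order
    top_score[i] = best;
    status[i] = 0;
    for (int r : best_refs) {
      read_out.push_back(i + 1);
      ref_out.push_back(r + 1);
    }
    if (i % 256 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["read_idx"] = wrap(read_out),
                      _["ref_idx"] = wrap(ref_out),
                      _["top_score"] = top_score, _["status"] = status,
                      _["n_candidates"] = n_candidates);
}

// Merge mate pairs. seq2rc/qual2rev are mate 2 already reverse-complemented
// (qualities reversed). Scans every overlap length o in
// [min_overlap, min(n1, n2)], scoring matches minus mismatches; the best
// score wins, ties broken toward the longer overlap. Rejections:
// status 1 = reads too short for any admissible overlap,
// 2 = best overlap exceeds max_mismatch_fraction. status 0 = merged.
// Consensus: agreement keeps the base with max quality; disagreement keeps
// the higher-quality base (and its quality); quality tie keeps the mate-1
// base with the min of the two qualities.
// [[Rcpp::export]]
List merge_pairs_cpp(CharacterVector seq1, CharacterVector qual1,
                     CharacterVector seq2rc, CharacterVector qual2rev,
                     int min_overlap, double max_mismatch_fraction) {
  const int n = seq1.size();
  CharacterVector mseq(n), mqual(n);
  IntegerVector overlap(n), mism(n), status(n);
  std::string out_s, out_q;

  for (int i = 0; i < n; ++i) {
    const char* s1 = CHAR(STRING_ELT(seq1, i));
    const char* q1 = CHAR(STRING_ELT(qual1, i));
    const char* s2 = CHAR(STRING_ELT(seq2rc, i));
    const char* q2 = CHAR(STRING_ELT(qual2rev, i));
    const int n1 = LENGTH(STRING_ELT(seq1, i));
    const int n2 = LENGTH(STRING_ELT(seq2rc, i));
    mseq[i] = NA_STRING;
    mqual[i] = NA_STRING;
    overlap[i] = NA_INTEGER;
    mism[i] = NA_INTEGER;
    const int omax = n1 < n2 ? n1 : n2;
    if (omax < min_overlap || min_overlap < 1) {
      status[i] = 1;
      continue;
    }
    int best_o = -1, best_score = INT32_MIN, best_mm = 0;
    for (int o = min_overlap; o <= omax; ++o) {
      // mate-1 suffix of length o vs mate-2rc prefix of length o
      const char* a = s1 + (n1 - o);
      int mm = 0;
      for (int p = 0; p < o; ++p)
        if (a[p] != s2[p]) ++mm;
      const int score = o - 2 * mm;  // matches - mismatches
      if (score > best_score || (score == best_score && o > best_o)) {
        best_score = score;
        best_o = o;
        best_mm = mm;
      }
    }
    if ((double)best_mm / (double)best_o > max_mismatch_fraction) {
      status[i] = 2;
      continue;
    }
    const int o = best_o;
    const int mlen = n1 + n2 - o;
    out_s.assign(s1, n1 - o);
    out_q.assign(q1, n1 - o);
    for (int p = 0; p < o; ++p) {
      const char c1 = s1[n1 - o + p], c2 = s2[p];
      const char cq1 = q1[n1 - o + p], cq2 = q2[p];
      if (c1 == c2) {
        out_s.push_back(c1);
        out_q.push_back(cq1 > cq2 ? cq1 : cq2);
      } else if (cq1 > cq2) {
        out_s.push_back(c1);
        out_q.push_back(cq1);
      } else if (cq2 > cq1) {
        out_s.push_back(c2);
        out_q.push_back(cq2);
      } else {
        out_s.push_back(c1);
        out_q.push_back(cq1 < cq2 ? cq1 : cq2);
      }
    }
    out_s.append(s2 + o, n2 - o);
    out_q.append(q2 + o, n2 - o);
    if ((int)out_s.size() != mlen) stop("internal merge length error");
    mseq[i] = out_s;
    mqual[i] = out_q;
    overlap[i] = o;
    mism[i] = best_mm;
    status[i] = 0;
    if (i % 1024 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["sequence"] = mseq, _["quality"] = mqual,
                      _["overlap_length"] = overlap,
                      _["mismatches_in_overlap"] = mism,
                      _["status"] = status);
}
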