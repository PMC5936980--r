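#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <vector>
using namespace Rcpp;

// Unit-cost edit-distance alignment of a query against a reference.
// The query is always aligned end to end; when free_ref_ends is true the
// reference may overhang on either side at no cost (semi-global mode).
// This one primitive serves three roles:
//   * barcode demultiplexing: query = barcode, ref = read-end window;
//   * tail trimming:          query = adapter affix, ref = read end;
//   * typing:                 query = allele amplicon, ref = read (the read's
//     unaligned tails are the free overhang; per-allele-column projections
//     come from the query-side traceback).
// free_ref_ends = false gives the classic global distance.

static int sg_distance_core(const std::string& q, const std::string& r,
                            bool free_ref_ends) {
  const int n = (int) q.size(), m = (int) r.size();
  std::vector<int> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = free_ref_ends ? 0 : j;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i;
    const char qc = q[i - 1];
    for (int j = 1; j <= m; ++j) {
      int d = prev[j - 1] + (qc == r[j - 1] ? 0 : 1);
      int up = prev[j] + 1;      // query base against a gap in ref
      int left = cur[j - 1] + 1; // ref base consumed against a gap in query
      if (up < d) d = up;
      if (left < d) d = left;
      cur[j] = d;
    }
    std::swap(prev, cur);
  }
  if (!free_ref_ends) return prev[m];
  int best = prev[0];
  for (int j = 1; j <= m; ++j) if (prev[j] < best) best = prev[j];
  return best;
}

// [[Rcpp::export(name = ".sg_distance_cpp")]]
int sg_distance_cpp(std::string query, std::string ref, bool free_ref_ends) {
  return sg_distance_core(query, ref, free_ref_ends);
}

// Distance matrix: queries x refs.
// [[Rcpp::export(name = ".sg_distance_matrix_cpp")]]
IntegerMatrix sg_distance_matrix_cpp(CharacterVector queries, CharacterVector refs,
                                     bool free_ref_ends) {
  const int nq = queries.size(), nr = refs.size();
  IntegerMatrix out(nq, nr);
  std::vector<std::string> rs(nr);
  for (int j = 0; j < nr; ++j) rs[j] = as<std::string>(refs[j]);
  for (int i = 0; i < nq; ++i) {
    std::string q = as<std::string>(queries[i]);
    for (int j = 0; j < nr; ++j) out(i, j) = sg_distance_core(q, rs[j], free_ref_ends);
  }
  return out;
}

// Full alignment with traceback. Reported from the query's coordinate frame:
//   q_cols    one char per query position: the aligned ref char, or '-' when
//             the query base has no ref partner (a gap in the ref);
//   q_sub_pos 0-based query positions aligned to a differing ref char;
//   q_ins_pos / q_ins_seq ref bases consumed between query positions,
//             keyed by the 0-based query position they precede;
//   ref_start / ref_end  0-based half-open aligned span on the reference.
// Traceback tie preference (query frame): match > substitution > gap-in-ref
// > gap-in-query; on ties of the end column the largest ref span wins.
// [[Rcpp::export(name = ".sg_align_cpp")]]
List sg_align_cpp(std::string q, std::string r, bool free_ref_ends) {
  const int n = (int) q.size(), m = (int) r.size();
  std::vector<std::vector<int32_t>> D(n + 1, std::vector<int32_t>(m + 1));
  for (int j = 0; j <= m; ++j) D[0][j] = free_ref_ends ? 0 : j;
  for (int i = 1; i <= n; ++i) {
    D[i][0] = i;
    const char qc = q[i - 1];
    for (int j = 1; j <= m; ++j) {
      int d = D[i - 1][j - 1] + (qc == r[j - 1] ? 0 : 1);
      int up = D[i - 1][j] + 1;
      int left = D[i][j - 1] + 1;
      if (up < d) d = up;
      if (left < d) d = left;
      D[i][j] = d;
    }
  }
  int j_end = m;
  if (free_ref_ends) {
    int best = D[n][0];
    j_end = 0;
    for (int j = 0; j <= m; ++j)
      if (D[n][j] <= best) { best = D[n][j]; j_end = j; } // largest j on ties
  }
  const int dist = D[n][j_end];

  int i = n, j = j_end;
  int nsub = 0, ngap_ref = 0, ngap_query = 0;
  std::string qcols(n, '.');
  std::vector<int> ins_pos_rev, sub_pos_rev;
  std::vector<std::string> ins_seq_rev;
  auto push_ins = [&](int pos, char c) {
    if (ins_pos_rev.empty() || ins_pos_rev.back() != pos) {
      ins_pos_rev.push_back(pos); ins_seq_rev.push_back("");
    }
    ins_seq_rev.back().push_back(c);
    ++ngap_query;
  };
  while (i > 0 || j > 0) {
    if (i == 0) {
      if (free_ref_ends) break;          // leading ref overhang is free
      push_ins(0, r[j - 1]); --j; continue;
    }
    if (j == 0) {
      qcols[i - 1] = '-'; ++ngap_ref; --i; continue;
    }
    const int d = D[i][j];
    const bool is_match = (q[i - 1] == r[j - 1]);
    if (is_match && D[i - 1][j - 1] == d) {
      qcols[i - 1] = r[j - 1]; --i; --j;
    } else if (!is_match && D[i - 1][j - 1] + 1 == d) {
      qcols[i - 1] = r[j - 1]; ++nsub; sub_pos_rev.push_back(i - 1); --i; --j;
    } else if (D[i - 1][j] + 1 == d) {
      qcols[i - 1] = '-'; ++ngap_ref; --i;
    } else {
      push_ins(i, r[j - 1]); --j;
    }
  }
  const int ref_start = j;

  const int nev = (int) ins_pos_rev.size();
  IntegerVector ins_pos(nev);
  CharacterVector ins_seq(nev);
  for (int k = 0; k < nev; ++k) {
    ins_pos[k] = ins_pos_rev[nev - 1 - k];
    std::string s = ins_seq_rev[nev - 1 - k];
    std::reverse(s.begin(), s.end());
    ins_seq[k] = s;
  }
  IntegerVector sub_pos((int) sub_pos_rev.size());
  for (int k = 0; k < (int) sub_pos_rev.size(); ++k)
    sub_pos[k] = sub_pos_rev[sub_pos_rev.size() - 1 - k];

  return List::create(
    _["distance"] = dist, _["ref_start"] = ref_start, _["ref_end"] = j_end,
    _["n_sub"] = nsub, _["n_gap_ref"] = ngap_ref, _["n_gap_query"] = ngap_query,
    _["q_cols"] = qcols, _["q_ins_pos"] = ins_pos, _["q_ins_seq"] = ins_seq,
    _["q_sub_pos"] = sub_pos);
}

// Batch: align one query (an allele) against many refs (reads).
// [[Rcpp::export(name = ".sg_align_to_refs_cpp")]]
List sg_align_to_refs_cpp(std::string query, CharacterVector refs,
                          bool free_ref_ends) {
  const int nr = refs.size();
  List out(nr);
  for (int i = 0; i < nr; ++i)
    out[i] = sg_align_cpp(query, as<std::string>(refs[i]), free_ref_ends);
  return out;
}
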