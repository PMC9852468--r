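#include <Rcpp.h>
#include <cstring>
#include <vector>
using namespace Rcpp;

// Fitting alignment of a read against an amplicon template: the read is
// aligned end-to-end, template overhangs at either end are free.  Affine
// gaps: a gap of length L costs gap_open + L * gap_ext (both negative).
//
// Deterministic traceback contract (ties):
//   diagonal (match/mismatch)  >  gap in read (deletion, consumes template)
//   >  gap in template (insertion, consumes read);
// among equal-scoring end columns the leftmost (smallest template index)
// is taken, which yields leftmost indel placement for the common cases.

static const int NEG_INF = -(1 << 28);

// [[Rcpp::export]]
List cpp_align_fit(std::string read, std::string tmpl,
                   int match, int mismatch, int gap_open, int gap_ext) {
  const int m = (int)read.size();
  const int n = (int)tmpl.size();
  if (m == 0 || n == 0)
    stop("empty read or template");

  // fast path: read is an exact substring of the template
  size_t hit = tmpl.find(read);
  if (hit != std::string::npos) {
    return List::create(
      _["score"]    = match * m,
      _["start"]    = (int)hit,
      _["end"]      = (int)hit + m,
      _["read_aln"] = read,
      _["tmpl_aln"] = read,
      _["nmatch"]   = m,
      _["aln_len"]  = m);
  }

  // H: best score ending at (i,j); E: gap in template (consumes read);
  // F: gap in read (consumes template). Row-rolling score arrays; byte
  // traceback matrices: tb in {0 diag, 1 F, 2 E}; tbE/tbF: 1 = extend.
  const int W = n + 1;
  std::vector<int> Hp(W), Ep(W), Hc(W), Ec(W);
  std::vector<unsigned char> tb((size_t)(m + 1) * W);
  std::vector<unsigned char> tbE((size_t)(m + 1) * W);
  std::vector<unsigned char> tbF((size_t)(m + 1) * W);

  for (int j = 0; j <= n; ++j) {        // free leading template
    Hp[j] = 0; Ep[j] = NEG_INF;
  }
  const int go = gap_open + gap_ext;

  for (int i = 1; i <= m; ++i) {
    const char rc = read[i - 1];
    unsigned char *tb_i = &tb[(size_t)i * W];
    unsigned char *tbE_i = &tbE[(size_t)i * W];
    unsigned char *tbF_i = &tbF[(size_t)i * W];
    // column 0: leading read overhang is penalized
    Ec[0] = gap_open + i * gap_ext;
    Hc[0] = Ec[0];
    tb_i[0] = 2; tbE_i[0] = (i > 1);
    int fprev = NEG_INF;                // F[i][0]
    int hdiag = Hp[0];                  // H[i-1][j-1]
    for (int j = 1; j <= n; ++j) {
      // E: gap in template, consumes read base i
      int e_open = Hp[j] + go, e_ext = Ep[j] + gap_ext;
      int e; unsigned char te;
      if (e_open >= e_ext) { e = e_open; te = 0; } else { e = e_ext; te = 1; }
      // F: gap in read, consumes template base j
      int f_open = Hc[j - 1] + go, f_ext = fprev + gap_ext;
      int f; unsigned char tf;
      if (f_open >= f_ext) { f = f_open; tf = 0; } else { f = f_ext; tf = 1; }
      // H: diagonal preferred on ties, then F (deletion), then E (insertion)
      int best = hdiag + (rc == tmpl[j - 1] ? match : mismatch);
      unsigned char dir = 0;
      if (f > best) { best = f; dir = 1; }
      if (e > best) { best = e; dir = 2; }
      hdiag = Hp[j];
      Hc[j] = best; Ec[j] = e; fprev = f;
      tb_i[j] = dir; tbE_i[j] = te; tbF_i[j] = tf;
    }
    std::swap(Hp, Hc); std::swap(Ep, Ec);
  }

  // end: best over last row, leftmost on ties (free trailing template)
  int best_j = 0, best = Hp[0];
  for (int j = 1; j <= n; ++j)
    if (Hp[j] > best) { best = Hp[j]; best_j = j; }

  // traceback
  std::string ra, ta;
  ra.reserve(m + n); ta.reserve(m + n);
  int i = m, j = best_j, state = 0; // 0 = H, 1 = F, 2 = E
  int nmatch = 0;
  while (i > 0) {
    size_t row = (size_t)i * W;
    if (state == 0) {
      unsigned char dir = tb[row + j];
      if (dir == 0) {
        ra.push_back(read[i - 1]); ta.push_back(tmpl[j - 1]);
        if (read[i - 1] == tmpl[j - 1]) ++nmatch;
        --i; --j;
      } else state = (dir == 1) ? 1 : 2;
    } else if (state == 1) {            // gap in read, consume template
      ra.push_back('-'); ta.push_back(tmpl[j - 1]);
      unsigned char ext = tbF[row + j];
      --j;
      if (!ext) state = 0;
    } else {                            // gap in template, consume read
      ra.push_back(read[i - 1]); ta.push_back('-');
      unsigned char ext = tbE[row + j];
      --i;
      if (!ext) state = 0;
    }
  }
  int start = j;                        // template bases skipped for free
  std::reverse(ra.begin(), ra.end());
  std::reverse(ta.begin(), ta.end());

  return List::create(
    _["score"]    = best,
    _["start"]    = start,
    _["end"]      = best_j,
    _["read_aln"] = ra,
    _["tmpl_aln"] = ta,
    _["nmatch"]   = nmatch,
    _["aln_len"]  = (int)ra.size());
}

// Best ungapped overlap merge of a read pair.  r2rc/q2rc are the mate's
// reverse complement and reversed qualities.  Overlap lengths are scanned
// from the longest possible down to min_overlap; the first (longest)
// overlap whose mismatch fraction is <= max_mismatch_frac wins.  At
// disagreeing positions the higher-quality base is taken (ties: read 1).
// [[Rcpp::export]]
List cpp_merge_pair(std::string r1, std::string q1,
                    std::string r2rc, std::string q2rc,
                    int min_overlap, double max_mismatch_frac) {
  const int n1 = (int)r1.size(), n2 = (int)r2rc.size();
  const int omax = std::min(n1, n2);
  for (int o = omax; o >= min_overlap; --o) {
    int mm = 0;
    const int off = n1 - o;
    const int allowed = (int)(max_mismatch_frac * o);
    bool ok = true;
    for (int k = 0; k < o; ++k) {
      if (r1[off + k] != r2rc[k] && ++mm > allowed) { ok = false; break; }
    }
    if (!ok) continue;
    // consensus over the overlap
    std::string seq = r1.substr(0, off);
    std::string qual = q1.substr(0, off);
    seq.reserve(n1 + n2 - o); qual.reserve(n1 + n2 - o);
    for (int k = 0; k < o; ++k) {
      char b1 = r1[off + k], b2 = r2rc[k];
      char c1 = q1[off + k], c2 = q2rc[k];
      if (b1 == b2) { seq.push_back(b1); qual.push_back(std::max(c1, c2)); }
      else if (c2 > c1) { seq.push_back(b2); qual.push_back(c2); }
      else { seq.push_back(b1); qual.push_back(c1); }
    }
    seq += r2rc.substr(o);
    qual += q2rc.substr(o);
    return List::create(_["ok"] = true, _["seq"] = seq, _["qual"] = qual,
                        _["overlap"] = o, _["mismatches"] = mm);
  }
  return List::create(_["ok"] = false, _["seq"] = "", _["qual"] = "",
                      _["overlap"] = 0, _["mismatches"] = NA_INTEGER);
}
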