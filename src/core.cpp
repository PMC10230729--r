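// Core desk-scale sequence engines: six-frame translation, Smith-Waterman
// local protein alignment with affine gaps, seeded translated search, and a
// canonical k-mer read-to-genome classifier.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstring>
#include <climits>
#include <cstdint>
#include "bacmine_types.h"

using namespace Rcpp;

// Standard genetic code indexed by a*16+b*4+c with A=0,C=1,G=2,T=3.
static const char CODON_TABLE[65] =
  "KNKNTTTTRSRSIIMIQHQHPPPPRRRRLLLLEDEDAAAAGGGGVVVV*Y*YSSSS*CWCLFLF";

static inline int base2bit(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': case 'a': return 'T';
    case 'C': case 'c': return 'G';
    case 'G': case 'g': return 'C';
    case 'T': case 't': return 'A';
    default: return 'N';
  }
}

// Translate one reading frame starting at `off` of `seq`; trailing partial
// codons are dropped, any codon containing a non-ACGT base becomes 'X'.
static std::string translate_frame(const char* seq, int n, int off) {
  std::string out;
  if (n - off < 3) return out;
  out.reserve((n - off) / 3);
  for (int i = off; i + 2 < n; i += 3) {
    int a = base2bit(seq[i]), b = base2bit(seq[i + 1]), c = base2bit(seq[i + 2]);
    out.push_back((a < 0 || b < 0 || c < 0) ? 'X' : CODON_TABLE[(a << 4) | (b << 2) | c]);
  }
  return out;
}

static std::string revcomp_str(const char* seq, int n) {
  std::string rc(n, 'N');
  for (int i = 0; i < n; ++i) rc[i] = comp_base(seq[n - 1 - i]);
  return rc;
}

// Six frames of one sequence: +1,+2,+3 then -1,-2,-3.
static void six_frames(const std::string& s, std::string out[6]) {
  const char* p = s.c_str();
  int n = (int)s.size();
  std::string rc = revcomp_str(p, n);
  for (int f = 0; f < 3; ++f) {
    out[f] = translate_frame(p, n, f);
    out[3 + f] = translate_frame(rc.c_str(), n, f);
  }
}

// [[Rcpp::export(name = ".translate_six_frames_cpp")]]
List translate_six_frames_cpp(CharacterVector seqs) {
  int n = seqs.size();
  List res(n);
  CharacterVector fr_names = CharacterVector::create("+1", "+2", "+3", "-1", "-2", "-3");
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    std::string fr[6];
    six_frames(s, fr);
    CharacterVector v(6);
    for (int f = 0; f < 6; ++f) v[f] = fr[f];
    v.attr("names") = fr_names;
    res[i] = v;
  }
  return res;
}

// ---- scoring lookup -------------------------------------------------------

// 128x128 score lookup built from an R substitution matrix. Residues not in
// the matrix alphabet score as the wildcard 'X' row; any pairing with a stop
// ('*') is forced to a large negative score so local alignments never extend
// across a stop codon.
struct ScoreLookup {
  int tab[128 * 128];
  inline int operator()(char a, char b) const {
    return tab[((unsigned char)a & 127) * 128 + ((unsigned char)b & 127)];
  }
};

static void build_lookup(const IntegerMatrix& m, ScoreLookup& lk) {
  std::vector<std::string> rn = as<std::vector<std::string> >(rownames(m));
  int idx[128];
  int xi = -1;
  for (size_t i = 0; i < rn.size(); ++i) if (rn[i] == "X") xi = (int)i;
  if (xi < 0) stop("substitution matrix must contain a wildcard 'X' row");
  for (int c = 0; c < 128; ++c) idx[c] = xi;
  for (size_t i = 0; i < rn.size(); ++i) {
    unsigned char c = (unsigned char)rn[i][0];
    idx[c & 127] = (int)i;
    idx[tolower(c) & 127] = (int)i;
  }
  const int STOP_PEN = -1000000;
  for (int a = 0; a < 128; ++a) {
    for (int b = 0; b < 128; ++b) {
      if ((char)a == '*' || (char)b == '*')
        lk.tab[a * 128 + b] = STOP_PEN;
      else
        lk.tab[a * 128 + b] = m(idx[a], idx[b]);
    }
  }
}

// ---- Smith-Waterman (Gotoh affine) with start tracking --------------------

struct AlnRes { int score, qs, qe, ss, se; };

// Local alignment; gap of length L costs gap_open + L*gap_extend.
// Deterministic tie-break: among equal-score cells prefer the lexicographically
// smallest (query start, subject start), then the earliest end (shortest).
static AlnRes sw_align_core(const char* q, int n, const char* s, int m,
                            const ScoreLookup& lk, int gap_open, int gap_extend) {
  const int NEG = INT_MIN / 4;
  std::vector<int> H(m + 1, 0), E(m + 1, NEG);
  std::vector<int> Hqs(m + 1, 0), Hss(m + 1, 0), Eqs(m + 1, 0), Ess(m + 1, 0);
  AlnRes best = {0, 0, 0, 0, 0};
  for (int i = 1; i <= n; ++i) {
    int diagH = H[0], diagQs = i - 1, diagSs = 0;
    H[0] = 0; Hqs[0] = i; Hss[0] = 0;
    int F = NEG, Fqs = 0, Fss = 0;
    for (int j = 1; j <= m; ++j) {
      // E: gap in query (move along subject)
      int eo = H[j - 1] - gap_open - gap_extend;
      int ee = E[j - 1] - gap_extend;
      if (eo >= ee) { E[j] = eo; Eqs[j] = Hqs[j - 1]; Ess[j] = Hss[j - 1]; }
      else { E[j] = ee; Eqs[j] = Eqs[j - 1]; Ess[j] = Ess[j - 1]; }
      // F: gap in subject (move along query); H[j], Hqs[j], Hss[j] still hold row i-1
      int fo = H[j] - gap_open - gap_extend;
      int fe = F - gap_extend;
      int Fqs_new, Fss_new;
      if (fo >= fe) { F = fo; Fqs_new = Hqs[j]; Fss_new = Hss[j]; }
      else { F = fe; Fqs_new = Fqs; Fss_new = Fss; }
      Fqs = Fqs_new; Fss = Fss_new;
      // H
      int sub = diagH + lk(q[i - 1], s[j - 1]);
      int subQs = (diagH == 0) ? i - 1 : diagQs;
      int subSs = (diagH == 0) ? j - 1 : diagSs;
      diagH = H[j]; diagQs = Hqs[j]; diagSs = Hss[j];
      int h, hqs, hss;
      if (sub >= E[j] && sub >= F && sub > 0) { h = sub; hqs = subQs; hss = subSs; }
      else if (E[j] >= F && E[j] > 0) { h = E[j]; hqs = Eqs[j]; hss = Ess[j]; }
      else if (F > 0) { h = F; hqs = Fqs; hss = Fss; }
      else { h = 0; hqs = i; hss = j; }
      H[j] = h; Hqs[j] = hqs; Hss[j] = hss;
      if (h > best.score ||
          (h > 0 && h == best.score &&
           (hqs < best.qs || (hqs == best.qs && hss < best.ss)))) {
        best.score = h; best.qs = hqs; best.ss = hss; best.qe = i; best.se = j;
      }
    }
  }
  if (best.score == 0) { best.qs = best.qe = best.ss = best.se = 0; }
  return best;
}

// [[Rcpp::export(name = ".sw_align_cpp")]]
IntegerVector sw_align_cpp(std::string query, std::string subject,
                           IntegerMatrix score_matrix, int gap_open, int gap_extend) {
  ScoreLookup lk;
  build_lookup(score_matrix, lk);
  AlnRes r = sw_align_core(query.c_str(), (int)query.size(),
                           subject.c_str(), (int)subject.size(),
                           lk, gap_open, gap_extend);
  return IntegerVector::create(
    _["score"] = r.score, _["qstart"] = r.qs, _["qend"] = r.qe,
    _["sstart"] = r.ss, _["send"] = r.se);
}

// ---- seeded translated search ---------------------------------------------

static inline bool seedable(char c) { return c >= 'A' && c <= 'Z' && c != 'X'; }

static inline uint32_t pack_seed(const char* p) {
  return ((uint32_t)(unsigned char)p[0] << 24) | ((uint32_t)(unsigned char)p[1] << 16) |
         ((uint32_t)(unsigned char)p[2] << 8) | (uint32_t)(unsigned char)p[3];
}

// Ungapped X-drop extension around a seed; cheap prefilter before full DP.
static int ungapped_ext(const char* q, int n, const char* s, int m,
                        int qp, int sp, int seed_len, const ScoreLookup& lk,
                        int xdrop) {
  int score = 0;
  for (int t = 0; t < seed_len; ++t) score += lk(q[qp + t], s[sp + t]);
  int best = score;
  int cur = score;
  for (int qi = qp + seed_len, si = sp + seed_len; qi < n && si < m; ++qi, ++si) {
    cur += lk(q[qi], s[si]);
    if (cur > best) best = cur;
    if (cur < best - xdrop || cur < -xdrop) break;
  }
  cur = best;
  int bestL = 0, curL = 0;
  for (int qi = qp - 1, si = sp - 1; qi >= 0 && si >= 0; --qi, --si) {
    curL += lk(q[qi], s[si]);
    if (curL > bestL) bestL = curL;
    if (curL < bestL - xdrop) break;
  }
  return best + bestL;
}

// Search nucleotide sequences (reads, genomes, contigs) against a protein
// database via six-frame translation. Candidate (frame, subject) pairs are
// found with exact 4-mer seeds and an ungapped prefilter, then rescored with
// full Smith-Waterman; with use_seeds = FALSE every pair is fully aligned.
// Keeps the best hit per (query, subject). Returns protein-space coordinates
// per frame plus each query's summed translated length.
// [[Rcpp::export(name = ".search_translated_cpp")]]
List search_translated_cpp(CharacterVector queries, CharacterVector db,
                           IntegerMatrix score_matrix, int gap_open, int gap_extend,
                           bool use_seeds, int min_ungapped, int min_report) {
  ScoreLookup lk;
  build_lookup(score_matrix, lk);
  const int SEED = 4;
  int nq = queries.size(), ns = db.size();
  std::vector<std::string> subj(ns);
  for (int j = 0; j < ns; ++j) subj[j] = as<std::string>(db[j]);

  // seed index: packed 4-mer -> list of (subject, position)
  std::unordered_map<uint32_t, std::vector<std::pair<int, int> > > seed_map;
  if (use_seeds) {
    for (int j = 0; j < ns; ++j) {
      const std::string& s = subj[j];
      for (int p = 0; p + SEED <= (int)s.size(); ++p) {
        bool ok = true;
        for (int t = 0; t < SEED; ++t) if (!seedable(s[p + t])) { ok = false; break; }
        if (ok) seed_map[pack_seed(s.c_str() + p)].push_back(std::make_pair(j, p));
      }
    }
  }

  std::vector<int> out_q, out_frame, out_subj, out_score;
  std::vector<int> out_qs, out_qe, out_ss, out_se, out_flen;
  IntegerVector mlen(nq);

  std::vector<int> stamp(ns, -1);
  std::vector<int> best_score(ns, 0), best_frame(ns), best_qs(ns), best_qe(ns),
    best_ss(ns), best_se(ns), best_flen(ns);
  int frame_vals[6] = {1, 2, 3, -1, -2, -3};

  for (int r = 0; r < nq; ++r) {
    std::string s = as<std::string>(queries[r]);
    std::string fr[6];
    six_frames(s, fr);
    int mtot = 0;
    for (int f = 0; f < 6; ++f) mtot += (int)fr[f].size();
    mlen[r] = mtot;
    std::vector<int> touched;
    for (int f = 0; f < 6; ++f) {
      const std::string& pep = fr[f];
      int L = (int)pep.size();
      if (L < 1) continue;
      std::vector<int> cand;
      if (use_seeds) {
        std::vector<char> done(ns, 0);
        for (int p = 0; p + SEED <= L; ++p) {
          bool ok = true;
          for (int t = 0; t < SEED; ++t) if (!seedable(pep[p + t])) { ok = false; break; }
          if (!ok) continue;
          std::unordered_map<uint32_t, std::vector<std::pair<int, int> > >::iterator it =
            seed_map.find(pack_seed(pep.c_str() + p));
          if (it == seed_map.end()) continue;
          for (size_t u = 0; u < it->second.size(); ++u) {
            int j = it->second[u].first;
            if (done[j]) continue;
            int sp = it->second[u].second;
            int ug = ungapped_ext(pep.c_str(), L, subj[j].c_str(), (int)subj[j].size(),
                                  p, sp, SEED, lk, 20);
            if (ug >= min_ungapped) { done[j] = 1; cand.push_back(j); }
          }
        }
      } else {
        for (int j = 0; j < ns; ++j) cand.push_back(j);
      }
      for (size_t u = 0; u < cand.size(); ++u) {
        int j = cand[u];
        AlnRes a = sw_align_core(pep.c_str(), L, subj[j].c_str(), (int)subj[j].size(),
                                 lk, gap_open, gap_extend);
        if (a.score <= 0) continue;
        if (stamp[j] != r) { stamp[j] = r; best_score[j] = 0; touched.push_back(j); }
        if (a.score > best_score[j]) {
          best_score[j] = a.score; best_frame[j] = frame_vals[f];
          best_qs[j] = a.qs; best_qe[j] = a.qe; best_ss[j] = a.ss; best_se[j] = a.se;
          best_flen[j] = L;
        }
      }
    }
    for (size_t u = 0; u < touched.size(); ++u) {
      int j = touched[u];
      if (best_score[j] < min_report) continue;
      out_q.push_back(r + 1); out_frame.push_back(best_frame[j]);
      out_subj.push_back(j + 1); out_score.push_back(best_score[j]);
      out_qs.push_back(best_qs[j]); out_qe.push_back(best_qe[j]);
      out_ss.push_back(best_ss[j]); out_se.push_back(best_se[j]);
      out_flen.push_back(best_flen[j]);
    }
    if ((r & 1023) == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["query"] = wrap(out_q), _["frame"] = wrap(out_frame),
    _["subject"] = wrap(out_subj), _["raw_score"] = wrap(out_score),
    _["qstart"] = wrap(out_qs), _["qend"] = wrap(out_qe),
    _["sstart"] = wrap(out_ss), _["send"] = wrap(out_se),
    _["frame_len"] = wrap(out_flen), _["query_mlen"] = mlen);
}

// ---- canonical k-mer index and classifier ---------------------------------

static const int32_t KMER_AMBIG = INT32_MIN;

// Roll over a sequence calling fn(canonical_kmer) for each valid k-mer.
template <class F>
static void for_canonical_kmers(const std::string& s, int k, F fn) {
  uint64_t fwd = 0, rev = 0;
  uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  int run = 0;
  int n = (int)s.size();
  for (int i = 0; i < n; ++i) {
    int b = base2bit(s[i]);
    if (b < 0) { run = 0; fwd = rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - b) << (2 * (k - 1)));
    if (++run >= k) fn(fwd < rev ? fwd : rev);
  }
}

// [[Rcpp::export(name = ".kmer_index_build_cpp")]]
XPtr<KmerIdx> kmer_index_build_cpp(CharacterVector genomes, IntegerVector species, int k) {
  if (k < 15 || k > 31 || k % 2 == 0) stop("k must be odd and in [15, 31]");
  KmerIdx* idx = new KmerIdx();
  idx->k = k;
  idx->n_genomes = genomes.size();
  idx->species = as<std::vector<int> >(species);
  for (int g = 0; g < genomes.size(); ++g) {
    std::string s = as<std::string>(genomes[g]);
    int gid = g + 1, sid = idx->species[g];
    std::unordered_map<uint64_t, int32_t>& m = idx->map;
    for_canonical_kmers(s, k, [&](uint64_t km) {
      std::unordered_map<uint64_t, int32_t>::iterator it = m.find(km);
      if (it == m.end()) { m[km] = gid; return; }
      int32_t own = it->second;
      if (own == KMER_AMBIG) return;
      if (own == gid) return;
      if (own > 0) {
        it->second = (idx->species[own - 1] == sid) ? -sid : KMER_AMBIG;
      } else { // species-owned
        if (-own != sid) it->second = KMER_AMBIG;
      }
    });
  }
  return XPtr<KmerIdx>(idx, true);
}

// Strict-plurality genome assignment over a read's canonical k-mers.
// Species-shared and ambiguous k-mers carry no genome-level vote.
// [[Rcpp::export(name = ".kmer_classify_cpp")]]
IntegerVector kmer_classify_cpp(XPtr<KmerIdx> idx, CharacterVector reads) {
  int G = idx->n_genomes, k = idx->k;
  std::vector<int> votes(G + 1, 0);
  IntegerVector out(reads.size(), NA_INTEGER);
  for (int r = 0; r < reads.size(); ++r) {
    std::string s = as<std::string>(reads[r]);
    if ((int)s.size() < k) continue;
    std::fill(votes.begin(), votes.end(), 0);
    const std::unordered_map<uint64_t, int32_t>& m = idx->map;
    for_canonical_kmers(s, k, [&](uint64_t km) {
      std::unordered_map<uint64_t, int32_t>::const_iterator it = m.find(km);
      if (it != m.end() && it->second > 0) votes[it->second]++;
    });
    int best = 0, bestg = 0;
    bool tie = false;
    for (int g = 1; g <= G; ++g) {
      if (votes[g] > best) { best = votes[g]; bestg = g; tie = false; }
      else if (votes[g] == best && best > 0) tie = true;
    }
    if (best > 0 && !tie) out[r] = bestg;
    if ((r & 4095) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// [[Rcpp::export(name = ".kmer_index_stats_cpp")]]
List kmer_index_stats_cpp(XPtr<KmerIdx> idx) {
  int64_t ng = 0, nsp = 0, na = 0;
  for (std::unordered_map<uint64_t, int32_t>::const_iterator it = idx->map.begin();
       it != idx->map.end(); ++it) {
    if (it->second == KMER_AMBIG) ++na;
    else if (it->second > 0) ++ng;
    else ++nsp;
  }
  return List::create(
    _["k"] = idx->k, _["n_genomes"] = idx->n_genomes,
    _["n_kmers"] = (double)idx->map.size(),
    _["n_genome_owned"] = (double)ng, _["n_species_owned"] = (double)nsp,
    _["n_ambiguous"] = (double)na);
}

static std::string decode_kmer(uint64_t km, int k) {
  static const char B[4] = {'A', 'C', 'G', 'T'};
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) { s[i] = B[km & 3]; km >>= 2; }
  return s;
}

// Text dump of the index (sorted for determinism): k-mer string + owner code.
// [[Rcpp::export(name = ".kmer_index_dump_cpp")]]
List kmer_index_dump_cpp(XPtr<KmerIdx> idx) {
  std::vector<std::pair<uint64_t, int32_t> > v(idx->map.begin(), idx->map.end());
  std::sort(v.begin(), v.end());
  CharacterVector kmers(v.size());
  IntegerVector owners(v.size());
  for (size_t i = 0; i < v.size(); ++i) {
    kmers[i] = decode_kmer(v[i].first, idx->k);
    owners[i] = (v[i].second == KMER_AMBIG) ? NA_INTEGER : v[i].second;
  }
  return List::create(_["kmer"] = kmers, _["owner"] = owners,
                      _["k"] = idx->k, _["species"] = wrap(idx->species));
}

// [[Rcpp::export(name = ".kmer_index_restore_cpp")]]
XPtr<KmerIdx> kmer_index_restore_cpp(CharacterVector kmers, IntegerVector owners,
                                     int k, IntegerVector species) {
  KmerIdx* idx = new KmerIdx();
  idx->k = k;
  idx->species = as<std::vector<int> >(species);
  idx->n_genomes = species.size();
  for (int i = 0; i < kmers.size(); ++i) {
    std::string s = as<std::string>(kmers[i]);
    uint64_t km = 0;
    for (int t = 0; t < k; ++t) km = (km << 2) | (uint64_t)base2bit(s[t]);
    idx->map[km] = (owners[i] == NA_INTEGER) ? KMER_AMBIG : owners[i];
  }
  return XPtr<KmerIdx>(idx, true);
}
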