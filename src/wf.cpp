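// Forward Wright-Fisher engine.
//
// State convention: rows = haplotypes (2N, individual i owns rows 2i, 2i+1),
// columns = segregating sites sorted by (chromosome, position), values 0/1
// (ancestral/derived). The R driver owns phase structure (burn-in, splits,
// founder bottlenecks, gamete pooling, re-introduction pulses); this file only
// advances one population by n_gens discrete generations with multinomial
// reproduction, partial selfing, Poisson crossovers, infinite-sites mutation
// with collision re-draw, and optional single-locus additive viability
// selection (fitness 1, 1+s, 1+2s).
//
// Collision handling: a new mutation never lands on a position that is
// currently segregating or fixed-derived here, nor on any position in the
// caller-supplied forbidden list (positions active in other populations of
// the same simulation). A position whose derived allele is lost is freed for
// re-use -- on a finite 1e5-bp coordinate grid the strict "one mutation per
// position ever" rule would exhaust the grid, while re-using a globally
// extinct position is biologically indistinguishable from a fresh mutation.
//
// All randomness comes from R's RNG so set.seed() in R gives bit-identical
// trajectories.

#include <Rcpp.h>
#include <unordered_set>
#include <algorithm>
#include <cstring>
using namespace Rcpp;

typedef unsigned char hapval;
typedef long long llong;

static const llong KEY_BASE = 4000000000LL; // > max chromosome length

static inline llong enc_key(int chrom, int pos) {
  return (llong)chrom * KEY_BASE + (llong)pos;
}

// uniform integer in [0, n)
static inline int runif_int(int n) {
  int k = (int)(unif_rand() * n);
  if (k >= n) k = n - 1;
  return k;
}

struct Pop {
  std::vector< std::vector<hapval> > rows; // 2N x S
  std::vector<llong> keys;                 // sorted
  std::vector<int> colchrom;               // 1-based
  std::vector<int> colpos;                 // 1-based
  int S() const { return (int)keys.size(); }
};

// copy one gamete from parent haplotype rows A/B into out, using crossover
// breakpoints per chromosome; columns [c0, c1) belong to chromosome c.
static void make_gamete(const std::vector<hapval>& A,
                        const std::vector<hapval>& B,
                        const std::vector<int>& colpos,
                        const std::vector<int>& chrom_col_begin, // n_chrom+1
                        const IntegerVector& chrom_len,
                        double rho,
                        std::vector<hapval>& out) {
  int n_chrom = chrom_len.size();
  for (int c = 0; c < n_chrom; ++c) {
    int c0 = chrom_col_begin[c], c1 = chrom_col_begin[c + 1];
    int h = (unif_rand() < 0.5) ? 0 : 1; // independent assortment
    int ncx = (rho > 0) ? (int)R::rpois(rho * chrom_len[c]) : 0;
    if (c1 == c0) continue;
    if (ncx == 0) {
      const std::vector<hapval>& src = h == 0 ? A : B;
      std::memcpy(&out[c0], &src[c0], (size_t)(c1 - c0));
      continue;
    }
    std::vector<double> bp(ncx);
    for (int k = 0; k < ncx; ++k) bp[k] = unif_rand() * chrom_len[c];
    std::sort(bp.begin(), bp.end());
    int seg = c0;
    for (int k = 0; k < ncx && seg < c1; ++k) {
      // first column with (1-based) position > bp[k]
      int idx = (int)(std::upper_bound(colpos.begin() + seg,
                                       colpos.begin() + c1,
                                       (int)bp[k]) - colpos.begin());
      if (idx > seg) {
        const std::vector<hapval>& src = h == 0 ? A : B;
        std::memcpy(&out[seg], &src[seg], (size_t)(idx - seg));
        seg = idx;
      }
      h = 1 - h;
    }
    if (seg < c1) {
      const std::vector<hapval>& src = h == 0 ? A : B;
      std::memcpy(&out[seg], &src[seg], (size_t)(c1 - seg));
    }
  }
}

// weighted parent draw from cumulative weights
static inline int draw_parent(const std::vector<double>& cumw) {
  double u = unif_rand() * cumw.back();
  return (int)(std::upper_bound(cumw.begin(), cumw.end(), u) - cumw.begin());
}

// [[Rcpp::export(name = ".wf_evolve_cpp")]]
List wf_evolve_cpp(IntegerMatrix H_in,
                   IntegerVector site_chrom,
                   IntegerVector site_pos,
                   IntegerVector chrom_len,
                   int n_gens,
                   int n_offspring,
                   double mu,
                   double rho,
                   double selfing,
                   int sweep_chrom,
                   int sweep_pos,
                   double sweep_s,
                   bool sweep_introduce,
                   bool stop_on_sweep_fix,
                   bool stop_on_sweep_loss,
                   NumericVector forbidden_keys) {
  const int n_chrom = chrom_len.size();
  double total_len = 0;
  std::vector<double> cumlen(n_chrom);
  for (int c = 0; c < n_chrom; ++c) {
    total_len += (double)chrom_len[c];
    cumlen[c] = total_len;
  }

  Pop pop;
  int n_hap = H_in.nrow();
  if (n_hap < 2 || n_hap % 2 != 0)
    stop("haplotype count must be even and >= 2");
  pop.rows.assign(n_hap, std::vector<hapval>(H_in.ncol()));
  for (int r = 0; r < n_hap; ++r)
    for (int j = 0; j < H_in.ncol(); ++j)
      pop.rows[r][j] = (hapval)H_in(r, j);
  pop.keys.resize(H_in.ncol());
  pop.colchrom.assign(site_chrom.begin(), site_chrom.end());
  pop.colpos.assign(site_pos.begin(), site_pos.end());
  for (int j = 0; j < H_in.ncol(); ++j)
    pop.keys[j] = enc_key(site_chrom[j], site_pos[j]);

  std::unordered_set<llong> forbidden;
  forbidden.reserve(forbidden_keys.size() + 16);
  for (double k : forbidden_keys) forbidden.insert((llong)k);
  std::unordered_set<llong> used(forbidden);
  used.reserve(forbidden.size() + pop.keys.size() + 4096);
  for (llong k : pop.keys) used.insert(k);

  std::vector<llong> fixed_keys;

  // sweep bookkeeping: 0 none, 1 segregating, 2 fixed, 3 lost
  int sweep_status = 0;
  llong sweep_key = 0;
  if (sweep_s > 0 && sweep_chrom >= 1) {
    sweep_key = enc_key(sweep_chrom, sweep_pos);
    if (sweep_introduce) {
      if (std::binary_search(pop.keys.begin(), pop.keys.end(), sweep_key))
        stop("sweep position collides with an existing segregating site");
      int at = (int)(std::lower_bound(pop.keys.begin(), pop.keys.end(),
                                      sweep_key) - pop.keys.begin());
      int carrier = runif_int(n_hap);
      pop.keys.insert(pop.keys.begin() + at, sweep_key);
      pop.colchrom.insert(pop.colchrom.begin() + at, sweep_chrom);
      pop.colpos.insert(pop.colpos.begin() + at, sweep_pos);
      for (int r = 0; r < n_hap; ++r)
        pop.rows[r].insert(pop.rows[r].begin() + at,
                           (hapval)(r == carrier ? 1 : 0));
      used.insert(sweep_key);
    } else if (!std::binary_search(pop.keys.begin(), pop.keys.end(),
                                   sweep_key)) {
      stop("sweep locus not segregating and sweep_introduce is FALSE");
    }
    sweep_status = 1;
  }

  const int n_hap_out = 2 * n_offspring;
  int gens_run = 0;
  int sweep_count = 0;

  std::vector<int> chrom_col_begin(n_chrom + 1);
  std::vector<double> cumw;
  std::vector< std::vector<hapval> > off;
  std::vector<int> cnt;

  for (int g = 0; g < n_gens; ++g) {
    int N_par = (int)pop.rows.size() / 2;
    int S = pop.S();

    // chromosome column ranges
    {
      int j = 0;
      for (int c = 0; c < n_chrom; ++c) {
        chrom_col_begin[c] = j;
        while (j < S && pop.colchrom[j] == c + 1) ++j;
        chrom_col_begin[c + 1] = j;
      }
    }

    // selection weights
    bool selected = false;
    int j_s = -1;
    if (sweep_status == 1) {
      j_s = (int)(std::lower_bound(pop.keys.begin(), pop.keys.end(),
                                   sweep_key) - pop.keys.begin());
      cumw.resize(N_par);
      double acc = 0;
      for (int i = 0; i < N_par; ++i) {
        int cnt_i = pop.rows[2 * i][j_s] + pop.rows[2 * i + 1][j_s];
        acc += 1.0 + sweep_s * cnt_i;
        cumw[i] = acc;
      }
      selected = true;
    }

    // offspring gametes
    off.assign(n_hap_out, std::vector<hapval>(S));
    std::vector< std::pair<llong, int> > muts; // key, haplotype index
    for (int i = 0; i < n_offspring; ++i) {
      int p1 = selected ? draw_parent(cumw) : runif_int(N_par);
      int p2 = (unif_rand() < selfing)
                   ? p1
                   : (selected ? draw_parent(cumw) : runif_int(N_par));
      make_gamete(pop.rows[2 * p1], pop.rows[2 * p1 + 1], pop.colpos,
                  chrom_col_begin, chrom_len, rho, off[2 * i]);
      make_gamete(pop.rows[2 * p2], pop.rows[2 * p2 + 1], pop.colpos,
                  chrom_col_begin, chrom_len, rho, off[2 * i + 1]);
    }
    // mutations (infinite sites: redraw on any collision, global registry)
    if (mu > 0) {
      for (int h = 0; h < n_hap_out; ++h) {
        int nmut = (int)R::rpois(mu * total_len);
        for (int m = 0; m < nmut; ++m) {
          llong key = 0;
          for (int tries = 0; tries < 10000; ++tries) {
            double u = unif_rand() * total_len;
            int c = (int)(std::lower_bound(cumlen.begin(), cumlen.end(), u) -
                          cumlen.begin());
            if (c >= n_chrom) c = n_chrom - 1;
            double prev = c == 0 ? 0.0 : cumlen[c - 1];
            int pos = 1 + (int)(u - prev);
            if (pos > chrom_len[c]) pos = chrom_len[c];
            llong k = enc_key(c + 1, pos);
            if (used.find(k) == used.end()) { key = k; break; }
          }
          if (key == 0) stop("mutation position space exhausted");
          used.insert(key);
          muts.push_back(std::make_pair(key, h));
        }
      }
    }
    std::sort(muts.begin(), muts.end());

    // allele counts; keep polymorphic columns
    cnt.assign(S, 0);
    for (int h = 0; h < n_hap_out; ++h) {
      const std::vector<hapval>& row = off[h];
      for (int j = 0; j < S; ++j) cnt[j] += row[j];
    }
    if (sweep_status == 1) {
      sweep_count = (j_s >= 0) ? cnt[j_s] : 0;
      if (sweep_count == n_hap_out) sweep_status = 2;
      else if (sweep_count == 0) sweep_status = 3;
    }

    std::vector<int> keep;
    keep.reserve(S);
    for (int j = 0; j < S; ++j) {
      if (cnt[j] == 0) { // globally lost here: free the position for re-use
        if (forbidden.find(pop.keys[j]) == forbidden.end())
          used.erase(pop.keys[j]);
        continue;
      }
      if (cnt[j] == n_hap_out) { fixed_keys.push_back(pop.keys[j]); continue; }
      keep.push_back(j);
    }

    // merge kept columns with new mutation columns (both key-sorted)
    int S_new = (int)keep.size() + (int)muts.size();
    std::vector<llong> nkeys(S_new);
    std::vector<int> nchrom(S_new), npos(S_new), src(S_new), mut_hap(S_new);
    {
      size_t a = 0, b = 0; int k = 0;
      while (a < keep.size() || b < muts.size()) {
        bool take_old = b >= muts.size() ||
          (a < keep.size() && pop.keys[keep[a]] < muts[b].first);
        if (take_old) {
          int j = keep[a++];
          nkeys[k] = pop.keys[j];
          nchrom[k] = pop.colchrom[j];
          npos[k] = pop.colpos[j];
          src[k] = j; mut_hap[k] = -1;
        } else {
          llong key = muts[b].first;
          nkeys[k] = key;
          nchrom[k] = (int)(key / KEY_BASE);
          npos[k] = (int)(key % KEY_BASE);
          src[k] = -1; mut_hap[k] = muts[b].second;
          ++b;
        }
        ++k;
      }
    }
    std::vector< std::vector<hapval> > next(n_hap_out,
                                            std::vector<hapval>(S_new));
    for (int h = 0; h < n_hap_out; ++h) {
      const std::vector<hapval>& orow = off[h];
      std::vector<hapval>& nrow = next[h];
      for (int k = 0; k < S_new; ++k)
        nrow[k] = src[k] >= 0 ? orow[src[k]] : (hapval)(mut_hap[k] == h);
    }
    pop.rows.swap(next);
    pop.keys.swap(nkeys);
    pop.colchrom.swap(nchrom);
    pop.colpos.swap(npos);
    ++gens_run;

    if (sweep_status == 2 && stop_on_sweep_fix) break;
    if (sweep_status == 3 && stop_on_sweep_loss) break;
    if (g % 64 == 63) Rcpp::checkUserInterrupt();
  }

  int S = pop.S();
  int n_out = (int)pop.rows.size();
  IntegerMatrix H_out(n_out, S);
  for (int r = 0; r < n_out; ++r)
    for (int j = 0; j < S; ++j) H_out(r, j) = pop.rows[r][j];
  IntegerVector out_chrom(pop.colchrom.begin(), pop.colchrom.end());
  IntegerVector out_pos(pop.colpos.begin(), pop.colpos.end());
  IntegerVector fx_chrom(fixed_keys.size()), fx_pos(fixed_keys.size());
  for (size_t i = 0; i < fixed_keys.size(); ++i) {
    fx_chrom[i] = (int)(fixed_keys[i] / KEY_BASE);
    fx_pos[i] = (int)(fixed_keys[i] % KEY_BASE);
  }
  return List::create(_["H"] = H_out,
                      _["chrom"] = out_chrom,
                      _["pos"] = out_pos,
                      _["fixed_chrom"] = fx_chrom,
                      _["fixed_pos"] = fx_pos,
                      _["sweep_status"] = sweep_status,
                      _["sweep_count"] = sweep_count,
                      _["gens_run"] = gens_run);
}
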