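#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Discrete-generation coalescent for microsatellites under a generalized
// stepwise mutation model (GSM).
//
// Time runs backward in whole generations. Within an interval between two
// demographic events every population has a constant diploid size Ne; with
// k lineages the waiting time to the next (pairwise) coalescence is
// 1 + Geometric(p) generations with p = min(1, k(k-1)/2 / (2 Ne)). Events
// either move all lineages of one population into another (divergence,
// seen backward) or send each lineage of a population to one of two
// sources with probability ra / 1-ra (admixture). Size changes (e.g.
// founder bottlenecks) are encoded as per-population piecewise-constant
// sizes whose breakpoints coincide with no-op events, so sizes are
// constant inside every interval.

static double pop_size_at(int pop, double t,
                          const IntegerVector& sz_pop,
                          const NumericVector& sz_time,
                          const NumericVector& sz_ne) {
  double ne = -1.0;
  for (int i = 0; i < sz_pop.size(); ++i) {
    if (sz_pop[i] == pop && sz_time[i] <= t + 1e-9) ne = sz_ne[i];
  }
  return ne;
}

static int gsm_step(int state, double gsm_p, int smin, int smax,
                    int boundary) {
  // step magnitude k >= 1 with P(k) = (1-P) P^(k-1), sign +/- equiprobable
  for (int tries = 0; tries < 1000; ++tries) {
    int k = 1 + (gsm_p > 0.0 ? (int)R::rgeom(1.0 - gsm_p) : 0);
    int sgn = (unif_rand() < 0.5) ? -1 : 1;
    int prop = state + sgn * k;
    if (prop >= smin && prop <= smax) return prop;
    if (boundary == 1) { // reflect
      while (prop < smin || prop > smax) {
        if (prop < smin) prop = 2 * smin - prop;
        if (prop > smax) prop = 2 * smax - prop;
      }
      return prop;
    }
    // boundary == 0: resample the step
  }
  return state; // pathological range; keep state
}

// [[Rcpp::export]]
IntegerMatrix cpp_simulate_msat(IntegerVector n_dip,       // per sampled pop
                                int npop_total,
                                NumericVector ev_time,     // ascending
                                IntegerVector ev_type,     // 0 move,1 admix,2 noop
                                IntegerVector ev_a,        // source pop
                                IntegerVector ev_b,        // dest / srcA
                                IntegerVector ev_c,        // srcB (admix)
                                NumericVector ev_ra,
                                IntegerVector sz_pop,
                                NumericVector sz_time,
                                NumericVector sz_ne,
                                NumericVector mu,          // per locus
                                double gsm_p,
                                int state_min, int state_max,
                                int founder_state,
                                int boundary) {
  int P = n_dip.size();
  int ncopies = 0;
  for (int p = 0; p < P; ++p) ncopies += 2 * n_dip[p];
  int L = mu.size();
  IntegerMatrix out(ncopies, L);
  int nev = ev_time.size();
  int nnodes_max = 2 * ncopies; // 2n-1 nodes + margin

  std::vector<int> parent(nnodes_max);
  std::vector<double> ntime(nnodes_max);

  for (int l = 0; l < L; ++l) {
    // initialise leaves
    std::vector< std::vector<int> > active(npop_total);
    int idx = 0;
    for (int p = 0; p < P; ++p)
      for (int c = 0; c < 2 * n_dip[p]; ++c) {
        active[p].push_back(idx);
        parent[idx] = -1; ntime[idx] = 0.0;
        ++idx;
      }
    int nnodes = ncopies;
    int e = 0;
    double t_cur = 0.0;
    int k_tot = ncopies;
    while (k_tot > 1) {
      double t_next = (e < nev) ? ev_time[e] : R_PosInf;
      // independent coalescence within each population up to t_next
      for (int p = 0; p < npop_total; ++p) {
        if ((int)active[p].size() < 2) continue;
        double ne = pop_size_at(p, t_cur, sz_pop, sz_time, sz_ne);
        if (ne <= 0) stop("population %d holds lineages but has no size",
                          p + 1);
        double tp = t_cur;
        int slots = (int)(2.0 * ne + 0.5);
        if (slots < 1) slots = 1;
        while ((int)active[p].size() >= 2) {
          double k = (double)active[p].size();
          double pc = k * (k - 1.0) / 2.0 / (2.0 * ne);
          if (pc > 0.3) {
            // dense regime: simulate one Wright-Fisher generation by
            // parent picking (keeps pair-coalescence marginals exact,
            // unlike capping the serial-pairwise rate at 1/generation)
            if (tp + 1.0 >= t_next) break;
            tp += 1.0;
            std::vector<int> slot_of(active[p].size());
            for (size_t i = 0; i < active[p].size(); ++i)
              slot_of[i] = (int)(unif_rand() * slots);
            // merge lineages sharing a parent slot
            std::vector<int> seen_slot, seen_node;
            std::vector<int> next_active;
            for (size_t i = 0; i < active[p].size(); ++i) {
              int s = slot_of[i];
              int found = -1;
              for (size_t u = 0; u < seen_slot.size(); ++u)
                if (seen_slot[u] == s) { found = (int)u; break; }
              if (found < 0) {
                seen_slot.push_back(s);
                seen_node.push_back(active[p][i]);
              } else {
                int ni = seen_node[found], nj = active[p][i];
                parent[ni] = nnodes; parent[nj] = nnodes;
                ntime[nnodes] = tp; parent[nnodes] = -1;
                seen_node[found] = nnodes;
                ++nnodes;
                --k_tot;
              }
            }
            active[p] = seen_node;
          } else {
            double wait = 1.0 + R::rgeom(pc);
            if (tp + wait >= t_next) break;
            tp += wait;
            // merge a uniform random pair
            int i = (int)(unif_rand() * active[p].size());
            int j;
            do { j = (int)(unif_rand() * active[p].size()); } while (j == i);
            int ni = active[p][i], nj = active[p][j];
            parent[ni] = nnodes; parent[nj] = nnodes;
            ntime[nnodes] = tp; parent[nnodes] = -1;
            if (i > j) std::swap(i, j);
            active[p].erase(active[p].begin() + j);
            active[p][i] = nnodes;
            ++nnodes;
            --k_tot;
          }
        }
      }
      if (k_tot == 1) break;
      if (e >= nev) {
        // no events left: all remaining lineages must share a population
        int npop_live = 0;
        for (int p = 0; p < npop_total; ++p)
          if (!active[p].empty()) ++npop_live;
        if (npop_live > 1)
          stop("disconnected scenario: lineages cannot coalesce");
        continue; // keep coalescing in the single terminal population
      }
      // apply event e at time t_next
      int type = ev_type[e];
      if (type == 0) { // move all lineages a -> b
        int a = ev_a[e], b = ev_b[e];
        for (size_t i = 0; i < active[a].size(); ++i)
          active[b].push_back(active[a][i]);
        active[a].clear();
      } else if (type == 1) { // admixture: a -> b with prob ra else c
        int a = ev_a[e], b = ev_b[e], c = ev_c[e];
        double ra = ev_ra[e];
        for (size_t i = 0; i < active[a].size(); ++i) {
          if (unif_rand() < ra) active[b].push_back(active[a][i]);
          else active[c].push_back(active[a][i]);
        }
        active[a].clear();
      } // type 2: no-op (size breakpoint marker)
      t_cur = t_next;
      ++e;
    }
    int root = nnodes - 1;
    // mutations: walk from root down (children have smaller indices)
    std::vector<int> state(nnodes);
    state[root] = founder_state;
    for (int i = nnodes - 2; i >= 0; --i) {
      double blen = ntime[parent[i]] - ntime[i];
      int s = state[parent[i]];
      int nmut = (int)R::rpois(mu[l] * blen);
      for (int m = 0; m < nmut; ++m)
        s = gsm_step(s, gsm_p, state_min, state_max, boundary);
      state[i] = s;
    }
    for (int i = 0; i < ncopies; ++i) out(i, l) = state[i];
  }
  return out;
}

static double unbiased_he_counts(const std::vector<int>& cnt, int tot) {
  if (tot < 2) return NA_REAL;
  double s2 = 0.0;
  for (size_t a = 0; a < cnt.size(); ++a) {
    double p = (double)cnt[a] / tot;
    s2 += p * p;
  }
  return (double)tot / (tot - 1.0) * (1.0 - s2);
}

// ABC summary statistics on integer allele matrices (NA allowed).
// Per group: mean alleles/locus A, mean unbiased He, mean allele-size
// variance, mean Garza-Williamson M = A/(range+1).
// Per group pair: Nei Fst (pairwise, ratio of locus means), (dmu)^2,
// shared-allele distance D_AS.
// [[Rcpp::export]]
NumericVector cpp_summary_stats(IntegerMatrix a1, IntegerMatrix a2,
                                IntegerVector grp, int G) {
  int n = a1.nrow(), L = a1.ncol();
  int npair = G * (G - 1) / 2;
  NumericVector out(4 * G + 3 * npair);
  int smin = 1000000000, smax = -1000000000;
  for (int i = 0; i < n; ++i)
    for (int l = 0; l < L; ++l)
      if (a1(i, l) != NA_INTEGER) {
        if (a1(i, l) < smin) smin = a1(i, l);
        if (a2(i, l) < smin) smin = a2(i, l);
        if (a1(i, l) > smax) smax = a1(i, l);
        if (a2(i, l) > smax) smax = a2(i, l);
      }
  int nall = smax - smin + 1;
  if (nall < 1) stop("no typed genotype");

  // per group per locus allele counts
  std::vector<double> meanA(G, 0), meanHe(G, 0), meanV(G, 0), meanM(G, 0);
  std::vector< std::vector<double> > msize(G, std::vector<double>(L, 0));
  std::vector< std::vector<int> > nloc(G, std::vector<int>(L, 0));
  // counts[g][l] over alleles
  std::vector< std::vector< std::vector<int> > > counts(
      G, std::vector< std::vector<int> >(L, std::vector<int>(nall, 0)));
  std::vector< std::vector<int> > hets(G, std::vector<int>(L, 0));
  for (int i = 0; i < n; ++i) {
    int g = grp[i];
    for (int l = 0; l < L; ++l) {
      if (a1(i, l) == NA_INTEGER) continue;
      counts[g][l][a1(i, l) - smin]++;
      counts[g][l][a2(i, l) - smin]++;
      nloc[g][l]++;
      if (a1(i, l) != a2(i, l)) hets[g][l]++;
    }
  }
  for (int g = 0; g < G; ++g) {
    int used = 0;
    for (int l = 0; l < L; ++l) {
      int tot = 2 * nloc[g][l];
      if (tot < 2) continue;
      ++used;
      int A = 0, lo = -1, hi = -1;
      double mean = 0, m2 = 0;
      for (int a = 0; a < nall; ++a) {
        int c = counts[g][l][a];
        if (c > 0) {
          ++A;
          if (lo < 0) lo = a;
          hi = a;
          mean += (double)c * (a + smin);
          m2 += (double)c * (a + smin) * (a + smin);
        }
      }
      mean /= tot; m2 /= tot;
      double var = (m2 - mean * mean) * tot / std::max(1, tot - 1);
      msize[g][l] = mean;
      meanA[g] += A;
      meanHe[g] += unbiased_he_counts(counts[g][l], tot);
      meanV[g] += var;
      meanM[g] += (double)A / (hi - lo + 1);
    }
    if (used > 0) {
      meanA[g] /= used; meanHe[g] /= used; meanV[g] /= used;
      meanM[g] /= used;
    } else {
      meanA[g] = NA_REAL; meanHe[g] = NA_REAL; meanV[g] = NA_REAL;
      meanM[g] = NA_REAL;
    }
    out[4 * g] = meanA[g];
    out[4 * g + 1] = meanHe[g];
    out[4 * g + 2] = meanV[g];
    out[4 * g + 3] = meanM[g];
  }

  // pairwise statistics
  int k = 4 * G;
  for (int g1 = 0; g1 < G - 1; ++g1) for (int g2 = g1 + 1; g2 < G; ++g2) {
    // Nei/Chesser pairwise Fst (ratio of locus means)
    double sHs = 0, sHt = 0; int usedf = 0;
    double dmu2 = 0; int usedd = 0;
    for (int l = 0; l < L; ++l) {
      int n1 = nloc[g1][l], n2 = nloc[g2][l];
      if (n1 < 1 || n2 < 1) continue;
      double nbar = 2.0 / (1.0 / n1 + 1.0 / n2);
      double ho = 0.5 * ((double)hets[g1][l] / n1 +
                         (double)hets[g2][l] / n2);
      double s2m = 0;
      double sp2 = 0;
      for (int a = 0; a < nall; ++a) {
        double p1 = (double)counts[g1][l][a] / (2 * n1);
        double p2 = (double)counts[g2][l][a] / (2 * n2);
        s2m += 0.5 * (p1 * p1 + p2 * p2);
        double pb = 0.5 * (p1 + p2);
        sp2 += pb * pb;
      }
      double hs = nbar / (nbar - 1.0) * (1.0 - s2m - ho / (2.0 * nbar));
      if (nbar <= 1.0) continue;
      double ht = 1.0 - sp2 + hs / (2.0 * nbar) - ho / (4.0 * nbar);
      sHs += hs; sHt += ht; ++usedf;
      double d = msize[g1][l] - msize[g2][l];
      dmu2 += d * d; ++usedd;
    }
    double fst = (usedf > 0 && sHt > 0) ? (sHt - sHs) / sHt : NA_REAL;
    double dm = (usedd > 0) ? dmu2 / usedd : NA_REAL;
    // D_AS across individual pairs
    double das_tot = 0; int das_n = 0;
    for (int i = 0; i < n; ++i) {
      if (grp[i] != g1) continue;
      for (int j = 0; j < n; ++j) {
        if (grp[j] != g2) continue;
        double s = 0; int nl = 0;
        for (int l = 0; l < L; ++l) {
          if (a1(i, l) == NA_INTEGER || a1(j, l) == NA_INTEGER) continue;
          int x1 = a1(i, l), x2 = a2(i, l), y1 = a1(j, l), y2 = a2(j, l);
          double sh = (x1 == y1) + (x1 == y2) + (x2 == y1) + (x2 == y2);
          if (x1 == x2 || y1 == y2) sh /= 2.0;
          s += sh / 2.0;
          ++nl;
        }
        if (nl > 0) { das_tot += s / nl; ++das_n; }
      }
    }
    double das = (das_n > 0) ? 1.0 - das_tot / das_n : NA_REAL;
    out[k] = fst; out[k + 1] = dm; out[k + 2] = das;
    k += 3;
  }
  return out;
}
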