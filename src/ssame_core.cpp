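// Compiled core of the reinforced subnetwork-sampling loop.
//
// Gene identifiers are mapped to 0-based indices by the R wrapper, with the
// gene universe sorted lexicographically so that index-ascending tie-breaks
// coincide with the documented lexicographic tie-breaks. All randomness is
// drawn from R's RNG stream (unif_rand), so set.seed() on the R side makes
// runs exactly reproducible.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct TopEntry {
  double mes;
  std::vector<int> genes;  // sorted ascending
};

// strictly better by (mes desc, sorted gene list lexicographically asc)
bool better(const TopEntry& a, const TopEntry& b) {
  if (a.mes != b.mes) return a.mes > b.mes;
  return a.genes < b.genes;
}

// MES of the member set: each pending sample contributes once with weight
// 1/m(s,V); genes processed by descending alteration count (index asc on
// ties) each collect the pending weight of their samples under a square
// root. m(s,V) is fixed on the full V; removal only affects the pending set.
double mes_members(const std::vector<int>& members,
                   const std::vector<std::vector<int>>& gene_samples,
                   std::vector<int>& msV, std::vector<int>& msV_epoch,
                   std::vector<int>& used_epoch, int& epoch,
                   double* buckets_out = nullptr) {
  ++epoch;
  for (int g : members) {
    for (int s : gene_samples[g]) {
      if (msV_epoch[s] != epoch) { msV_epoch[s] = epoch; msV[s] = 0; }
      ++msV[s];
    }
  }
  std::vector<int> order(members);
  std::sort(order.begin(), order.end(), [&](int a, int b) {
    size_t ca = gene_samples[a].size(), cb = gene_samples[b].size();
    if (ca != cb) return ca > cb;
    return a < b;
  });
  double total = 0.0;
  for (size_t i = 0; i < order.size(); ++i) {
    int g = order[i];
    double bucket = 0.0;
    for (int s : gene_samples[g]) {
      if (used_epoch[s] != epoch) {       // sample still pending
        used_epoch[s] = epoch;            // contributes once, then removed
        bucket += 1.0 / msV[s];
      }
    }
    total += std::sqrt(bucket);
    if (buckets_out) buckets_out[i] = bucket;
  }
  return total;
}

}  // namespace

// [[Rcpp::export]]
double cpp_mes_single(List gene_samples_r, int n_samples) {
  int k = gene_samples_r.size();
  std::vector<std::vector<int>> gs(k);
  for (int i = 0; i < k; ++i)
    gs[i] = as<std::vector<int>>(gene_samples_r[i]);
  std::vector<int> msV(n_samples, 0), msV_epoch(n_samples, 0),
      used_epoch(n_samples, 0);
  int epoch = 0;
  std::vector<int> members(k);
  for (int i = 0; i < k; ++i) members[i] = i;
  return mes_members(members, gs, msV, msV_epoch, used_epoch, epoch);
}

// [[Rcpp::export]]
List cpp_run(List adj_r, List gene_samples_r, int n_samples,
             IntegerVector seeds_r, IntegerVector sizes_r,
             double f, double r, int iterations,
             int stop_top_k, int stop_patience) {
  RNGScope rngscope;
  const int n = adj_r.size();
  std::vector<std::vector<int>> adj(n), gene_samples(n);
  for (int i = 0; i < n; ++i) {
    adj[i] = as<std::vector<int>>(adj_r[i]);
    gene_samples[i] = as<std::vector<int>>(gene_samples_r[i]);
  }
  std::vector<int> seeds = as<std::vector<int>>(seeds_r);
  std::vector<int> sizes = as<std::vector<int>>(sizes_r);

  std::vector<double> score(n, 0.5), best(n, 0.0), run_max(n, 0.5);
  std::vector<float> traj((size_t)n * iterations, 0.0f);
  std::vector<int> msV(n_samples, 0), msV_epoch(n_samples, 0),
      used_epoch(n_samples, 0);
  int epoch = 0;
  std::vector<int> member_flag(n, 0), frontier_flag(n, 0);
  int flag_epoch = 0;
  std::vector<std::vector<TopEntry>> top(n);
  std::vector<int> grow_attempts(iterations, 0), mes_evals(iterations, 0);
  std::vector<double> mean_score(iterations, 0.0);
  std::vector<int> n_high(iterations, 0);

  // per-iteration batch
  std::vector<double> batch_mes;
  std::vector<std::vector<int>> batch_members;
  std::vector<int> frontier, members;
  std::vector<int> prev_top, cur_top, ord(n);
  int stable = 0, T_ran = iterations;

  for (int it = 0; it < iterations; ++it) {
    const int sz = sizes[it % sizes.size()];
    batch_mes.clear();
    batch_members.clear();
    for (int seed : seeds) {
      ++grow_attempts[it];
      ++flag_epoch;
      members.clear();
      members.push_back(seed);
      member_flag[seed] = flag_epoch;
      while ((int)members.size() < sz) {
        frontier.clear();
        double total_w = 0.0;
        for (int m : members) {
          for (int nb : adj[m]) {
            if (member_flag[nb] != flag_epoch && frontier_flag[nb] != flag_epoch) {
              frontier_flag[nb] = flag_epoch;
              frontier.push_back(nb);
              total_w += score[nb];
            }
          }
        }
        if (frontier.empty()) break;
        int pick;
        if (total_w > 0.0) {
          double u = unif_rand() * total_w, acc = 0.0;
          pick = frontier.back();
          for (int cand : frontier) {
            acc += score[cand];
            if (u <= acc) { pick = cand; break; }
          }
        } else {  // zero-mass frontier: uniform draw so growth never stalls
          int idx = (int)(unif_rand() * frontier.size());
          if (idx >= (int)frontier.size()) idx = frontier.size() - 1;
          pick = frontier[idx];
        }
        members.push_back(pick);
        member_flag[pick] = flag_epoch;
      }
      if ((int)members.size() < 2) continue;  // isolated seed: no subnetwork
      double m = mes_members(members, gene_samples, msV, msV_epoch,
                             used_epoch, epoch);
      ++mes_evals[it];
      batch_mes.push_back(m);
      batch_members.push_back(members);
    }

    // rank MES within the iteration's batch -> rMES in [0,1]
    const int B = batch_mes.size();
    std::vector<double> rmes(B, 1.0);
    if (B > 1) {
      std::vector<int> bord(B);
      for (int i = 0; i < B; ++i) bord[i] = i;
      std::sort(bord.begin(), bord.end(), [&](int a, int b) {
        return batch_mes[a] < batch_mes[b];
      });
      int i = 0;
      while (i < B) {
        int j = i;
        while (j + 1 < B && batch_mes[bord[j + 1]] == batch_mes[bord[i]]) ++j;
        double avg_rank = (i + j) / 2.0 + 1.0;  // mean of ascending ranks
        for (int t = i; t <= j; ++t)
          rmes[bord[t]] = (avg_rank - 1.0) / (B - 1.0);
        i = j + 1;
      }
    }

    // best rMES per gene; genes in no subnetwork keep best = 0
    ++flag_epoch;
    for (int b = 0; b < B; ++b) {
      for (int g : batch_members[b]) {
        if (member_flag[g] != flag_epoch) {
          member_flag[g] = flag_epoch;
          best[g] = rmes[b];
        } else if (rmes[b] > best[g]) {
          best[g] = rmes[b];
        }
      }
    }
    double ssum = 0.0;
    int high = 0;
    for (int g = 0; g < n; ++g) {
      double bg = (member_flag[g] == flag_epoch) ? best[g] : 0.0;
      double s = f * score[g] + r * bg;
      if (s > 1.0) s = 1.0;  // topped off: scores never exceed 1
      score[g] = s;
      if (s > run_max[g]) run_max[g] = s;
      traj[(size_t)it * n + g] = (float)s;
      ssum += s;
      if (s > 0.9) ++high;
    }
    mean_score[it] = ssum / n;
    n_high[it] = high;

    // retain the 5 highest-MES subnetworks per member gene (global, all
    // iterations), deterministic tie-break on (MES, sorted gene list)
    for (int b = 0; b < B; ++b) {
      TopEntry e;
      e.mes = batch_mes[b];
      e.genes = batch_members[b];
      std::sort(e.genes.begin(), e.genes.end());
      for (int g : batch_members[b]) {
        auto& lst = top[g];
        if ((int)lst.size() < 5) {
          lst.push_back(e);
        } else {
          int worst = 0;
          for (int i = 1; i < 5; ++i)
            if (better(lst[worst], lst[i])) worst = i;
          if (better(e, lst[worst])) lst[worst] = e;
        }
      }
    }

    // early stop: top-k set by (score desc, index asc) unchanged for
    // stop_patience consecutive iterations
    if (stop_patience > 0) {
      int k = std::min(stop_top_k, n);
      for (int g = 0; g < n; ++g) ord[g] = g;
      std::partial_sort(ord.begin(), ord.begin() + k, ord.end(),
                        [&](int a, int b) {
                          if (score[a] != score[b]) return score[a] > score[b];
                          return a < b;
                        });
      cur_top.assign(ord.begin(), ord.begin() + k);
      std::sort(cur_top.begin(), cur_top.end());
      if (cur_top == prev_top) ++stable; else stable = 0;
      prev_top = cur_top;
      if (stable >= stop_patience) { T_ran = it + 1; break; }
    }
    if (it % 256 == 0) Rcpp::checkUserInterrupt();
  }

  // post-hoc per-gene summaries from the stored trajectory
  NumericVector max_score(n), final_score(n);
  IntegerVector conv(n);
  for (int g = 0; g < n; ++g) {
    // running max kept in double precision (initialization 0.5 included);
    // the float trajectory is only used for the convergence scan
    double mx = run_max[g];
    double thr = 0.99 * mx;
    int last_below = 0;
    for (int t = 0; t < T_ran; ++t)
      if ((double)traj[(size_t)t * n + g] < thr) last_below = t + 1;
    max_score[g] = mx;
    conv[g] = last_below + 1;  // T_ran + 1 == never settled
    final_score[g] = score[g];
  }

  List top_out(n);
  for (int g = 0; g < n; ++g) {
    std::sort(top[g].begin(), top[g].end(),
              [](const TopEntry& a, const TopEntry& b) { return better(a, b); });
    List lst(top[g].size());
    for (size_t i = 0; i < top[g].size(); ++i) {
      IntegerVector gv(top[g][i].genes.begin(), top[g][i].genes.end());
      lst[i] = List::create(_["mes"] = top[g][i].mes, _["genes"] = gv + 1);
    }
    top_out[g] = lst;
  }

  auto head_int = [&](std::vector<int>& v) {
    return IntegerVector(v.begin(), v.begin() + T_ran);
  };
  return List::create(
      _["score"] = final_score,
      _["max_score"] = max_score,
      _["convergence_iter"] = conv,
      _["n_iterations"] = T_ran,
      _["grow_attempts"] = head_int(grow_attempts),
      _["mes_evaluations"] = head_int(mes_evals),
      _["mean_score"] = NumericVector(mean_score.begin(),
                                      mean_score.begin() + T_ran),
      _["n_high"] = head_int(n_high),
      _["top_subnetworks"] = top_out);
}
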