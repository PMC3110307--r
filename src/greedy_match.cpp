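#include <Rcpp.h>
#include <set>
#include <cmath>

using namespace Rcpp;

// Greedy 1:1 nearest-neighbor matching without replacement on a scalar
// distance (the logit propensity score). Treated subjects are processed in
// the order given; each takes the closest still-available control within the
// caliper. Distance ties are broken in favour of the lower control index.
//
// ps_treated, ps_control: logit propensity scores.
// order: 0-based processing order over treated subjects.
// caliper: maximum |difference| allowed (>= 0).
// Returns a 0-based control index per treated subject, -1 if unmatched.
// [[Rcpp::export(name = ".greedy_match_cpp")]]
IntegerVector greedy_match_cpp(NumericVector ps_treated,
                               NumericVector ps_control,
                               IntegerVector order,
                               double caliper) {
  int n_t = ps_treated.size();
  IntegerVector match(n_t, -1);
  // available controls ordered by (score, original index)
  std::set<std::pair<double, int> > avail;
  for (int j = 0; j < ps_control.size(); ++j)
    avail.insert(std::make_pair(ps_control[j], j));

  for (int k = 0; k < n_t && !avail.empty(); ++k) {
    int i = order[k];
    double v = ps_treated[i];
    std::set<std::pair<double, int> >::iterator right =
        avail.lower_bound(std::make_pair(v, -1));
    bool has_right = right != avail.end();
    bool has_left = right != avail.begin();
    std::set<std::pair<double, int> >::iterator left = right;
    if (has_left) --left;

    if (!has_right && !has_left) continue;
    double d_r = has_right ? std::abs(right->first - v) : R_PosInf;
    double d_l = has_left ? std::abs(v - left->first) : R_PosInf;
    double d = d_r < d_l ? d_r : d_l;
    if (d > caliper) continue;
    // lowest-index control at the winning distance: several controls may
    // share the nearest value, and both sides may be equidistant
    std::set<std::pair<double, int> >::iterator best = avail.end();
    if (has_right && d_r == d) best = right;  // smallest index at its value
    if (has_left && d_l == d) {
      std::set<std::pair<double, int> >::iterator lo =
          avail.lower_bound(std::make_pair(left->first, -1));
      if (best == avail.end() || lo->second < best->second) best = lo;
    }
    match[i] = best->second;
    avail.erase(best);
  }
  return match;
}
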