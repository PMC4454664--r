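#include <Rcpp.h>
#include <vector>
#include <set>
#include "model_core.h"

using namespace Rcpp;

// Discrete-time scheduler for the marriage-market model. One call runs a
// single replicate from an initial population to the last simulation step,
// recording a census of married couples at the end of each census year and
// (optionally) the final population state for invariant checks.
//
// All randomness comes from R's RNG (unif_rand), so a run is fully
// reproducible from set.seed() on the R side. Draws are consumed in a fixed
// order within each step: death draws in agent index order; replacement
// attribute draws in index order; the search-phase shuffle; then per seeker
// the seek draw, the stratum draw, the candidate draw and the two dating
// draws; finally marriage draws in couple index order.

namespace {

inline int sample_cat(const double *p, int k) {
  double u = unif_rand(), acc = 0.0;
  for (int i = 0; i < k; ++i) {
    acc += p[i];
    if (u < acc) return i + 1;
  }
  return k;
}

inline int sample_index(const std::vector<int> &v) {
  int m = (int)v.size();
  int j = (int)(unif_rand() * m);
  if (j >= m) j = m - 1;
  return v[j];
}

inline void shuffle_indices(std::vector<int> &v) {
  for (int i = (int)v.size() - 1; i > 0; --i) {
    int j = (int)(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(v[i], v[j]);
  }
}

} // namespace

// [[Rcpp::export]]
List cpp_run_marriage_market(
    IntegerVector gender0, NumericVector age0, IntegerVector edu0,
    IntegerVector earn0, IntegerVector birth_year0,
    NumericMatrix edu_dist_m, NumericMatrix edu_dist_f, int first_sched_year,
    NumericMatrix earn_dist_m, NumericMatrix earn_dist_f,
    NumericVector w_s, NumericVector w_y, NumericVector w_a,
    double male_ideal, double female_offset, int ideal_rule,
    double s_max, double y_max, double a_max,
    NumericVector beta, NumericVector sigma, double delta,
    NumericVector d, NumericVector w_d,
    double a_marr, int start_year, int steps_per_year, int n_steps,
    IntegerVector census_steps, bool return_state) {

  const int n = gender0.size();
  std::vector<int> gender(gender0.begin(), gender0.end());
  std::vector<double> age(age0.begin(), age0.end());
  std::vector<int> edu(edu0.begin(), edu0.end());
  std::vector<int> earn(earn0.begin(), earn0.end());
  std::vector<int> byear(birth_year0.begin(), birth_year0.end());
  std::vector<int> enrol(n), status(n, 1), partner(n, -1);
  std::vector<double> reldur(n, 0.0);
  std::vector<char> proposed(n, 0), dead(n, 0);

  const int n_sched_years = edu_dist_m.nrow();

  for (int i = 0; i < n; ++i)
    enrol[i] = eamsim::enrolment_status(age[i], edu[i]);

  auto ideal_age = [&](int i) {
    return eamsim::ideal_partner_age(gender[i], age[i], male_ideal,
                                     female_offset, ideal_rule);
  };
  auto mv = [&](int i, int j) {
    int g = gender[i] - 1;
    return eamsim::mate_value(edu[i], edu[j], earn[j], ideal_age(i), age[j],
                              w_s[g], w_y[g], w_a[g], s_max, y_max, a_max);
  };
  auto make_single = [&](int i) {
    status[i] = 1;
    partner[i] = -1;
    reldur[i] = 0.0;
    proposed[i] = 0;
  };

  // census accumulators
  std::vector<int> c_year, c_medu, c_fedu, c_mby, c_fby;
  std::vector<double> c_mage, c_fage, c_dur;

  std::set<int> census_set(census_steps.begin(), census_steps.end());
  std::vector<int> order;
  order.reserve(n);

  for (int t = 1; t <= n_steps; ++t) {
    int year = start_year + (t - 1) / steps_per_year;

    // (1) ageing and removal at the age ceiling, (2) mortality
    for (int i = 0; i < n; ++i) {
      age[i] += 1.0;
      if (age[i] >= a_max) {
        dead[i] = 1;
      } else {
        int g = gender[i] - 1;
        double pd = eamsim::death_probability_step(age[i], d[g], w_d[g], a_max);
        dead[i] = (unif_rand() < pd) ? 1 : 0;
      }
    }
    // widow(er)s and abandoned partners of the deceased become single
    for (int i = 0; i < n; ++i)
      if (dead[i] && partner[i] >= 0 && !dead[partner[i]])
        make_single(partner[i]);

    // (3) replacement: same gender, born now, attributes drawn from the
    // current year's cohort schedule
    for (int i = 0; i < n; ++i) {
      if (!dead[i]) continue;
      int yi = year - first_sched_year;
      if (yi < 0) yi = 0;
      if (yi >= n_sched_years) yi = n_sched_years - 1;
      bool male = gender[i] == 1;
      NumericMatrix &ed = male ? edu_dist_m : edu_dist_f;
      NumericMatrix &ea = male ? earn_dist_m : earn_dist_f;
      double ep[4] = {ed(yi, 0), ed(yi, 1), ed(yi, 2), ed(yi, 3)};
      int s = sample_cat(ep, 4);
      double yp[5] = {ea(s - 1, 0), ea(s - 1, 1), ea(s - 1, 2), ea(s - 1, 3),
                      ea(s - 1, 4)};
      earn[i] = sample_cat(yp, 5);
      edu[i] = s;
      age[i] = 0.0;
      byear[i] = year;
      make_single(i);
      dead[i] = 0;
    }

    // (4) enrolment refresh (female ideal ages are recomputed on the fly)
    for (int i = 0; i < n; ++i)
      enrol[i] = eamsim::enrolment_status(age[i], edu[i]);

    // (5) search phase: marriageable agents in random order
    order.clear();
    for (int i = 0; i < n; ++i)
      if (age[i] >= a_marr) order.push_back(i);
    shuffle_indices(order);

    std::vector<int> same_r, diff_r;
    for (int oi = 0; oi < (int)order.size(); ++oi) {
      int i = order[oi];
      int g = gender[i] - 1;
      if (unif_rand() >= eamsim::seek_probability(reldur[i], beta[g]))
        continue;

      // structured meeting: stratify the eligible pool by shared enrolment
      same_r.clear();
      diff_r.clear();
      for (int j = 0; j < n; ++j) {
        if (gender[j] == gender[i] || age[j] < a_marr || j == partner[i])
          continue;
        (enrol[j] == enrol[i] ? same_r : diff_r).push_back(j);
      }
      bool pick_same = unif_rand() < delta;
      std::vector<int> *pool = pick_same ? &same_r : &diff_r;
      if (pool->empty()) pool = pick_same ? &diff_r : &same_r;
      if (pool->empty()) continue;
      int j = sample_index(*pool);

      // mutual dating decision; partnered agents only consider strictly
      // better alternatives
      double vij = mv(i, j);
      if (!(status[i] == 1 || vij > mv(i, partner[i]))) continue;
      double vji = mv(j, i);
      if (!(status[j] == 1 || vji > mv(j, partner[j]))) continue;
      int gj = gender[j] - 1;
      bool ok_i = unif_rand() < eamsim::date_probability(age[i], vij,
                                                         reldur[i], sigma[g],
                                                         beta[g]);
      bool ok_j = unif_rand() < eamsim::date_probability(age[j], vji,
                                                         reldur[j], sigma[gj],
                                                         beta[gj]);
      if (!(ok_i && ok_j)) continue;

      // both leave current partners and form a new dating couple
      if (partner[i] >= 0) make_single(partner[i]);
      if (partner[j] >= 0) make_single(partner[j]);
      status[i] = status[j] = 2;
      partner[i] = j;
      partner[j] = i;
      reldur[i] = reldur[j] = 0.0;
      proposed[i] = proposed[j] = 0;
    }

    // (6) marriage decisions for dating couples; a proposal, once made,
    // stands until accepted or the couple dissolves
    for (int i = 0; i < n; ++i) {
      int p = partner[i];
      if (p <= i || status[i] != 2) continue;
      if (!proposed[i]) {
        int g = gender[i] - 1;
        if (unif_rand() < eamsim::marry_probability(age[i], mv(i, p),
                                                    reldur[i], sigma[g],
                                                    beta[g]))
          proposed[i] = 1;
      }
      if (!proposed[p]) {
        int g = gender[p] - 1;
        if (unif_rand() < eamsim::marry_probability(age[p], mv(p, i),
                                                    reldur[p], sigma[g],
                                                    beta[g]))
          proposed[p] = 1;
      }
      if (proposed[i] && proposed[p]) {
        status[i] = status[p] = 3;
        proposed[i] = proposed[p] = 0;
      }
    }

    // (7) relationship durations accumulate
    for (int i = 0; i < n; ++i)
      if (partner[i] >= 0) reldur[i] += 1.0;

    // census of married couples at the end of a census year
    if (census_set.count(t)) {
      int cy = start_year + (t - 1) / steps_per_year;
      for (int i = 0; i < n; ++i) {
        int p = partner[i];
        if (status[i] == 3 && p >= 0 && gender[i] == 1) {
          c_year.push_back(cy);
          c_medu.push_back(edu[i]);
          c_fedu.push_back(edu[p]);
          c_mby.push_back(byear[i]);
          c_fby.push_back(byear[p]);
          c_mage.push_back(age[i]);
          c_fage.push_back(age[p]);
          c_dur.push_back(reldur[i]);
        }
      }
    }
  }

  DataFrame census = DataFrame::create(
      _["census_year"] = c_year, _["male_education"] = c_medu,
      _["female_education"] = c_fedu, _["male_birth_year"] = c_mby,
      _["female_birth_year"] = c_fby, _["male_age"] = c_mage,
      _["female_age"] = c_fage, _["rel_duration"] = c_dur);

  if (!return_state) return List::create(_["census"] = census);

  DataFrame state = DataFrame::create(
      _["gender"] = IntegerVector(gender.begin(), gender.end()),
      _["age"] = NumericVector(age.begin(), age.end()),
      _["education"] = IntegerVector(edu.begin(), edu.end()),
      _["earnings"] = IntegerVector(earn.begin(), earn.end()),
      _["enrolment"] = IntegerVector(enrol.begin(), enrol.end()),
      _["rel_status"] = IntegerVector(status.begin(), status.end()),
      _["partner"] = IntegerVector(partner.begin(), partner.end()),
      _["rel_duration"] = NumericVector(reldur.begin(), reldur.end()),
      _["birth_year"] = IntegerVector(byear.begin(), byear.end()));
  return List::create(_["census"] = census, _["state"] = state);
}
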