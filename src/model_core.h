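#ifndef EAMSIM_MODEL_CORE_H
#define EAMSIM_MODEL_CORE_H

#include <cmath>
#include <algorithm>

// Behavioural and demographic equations of the marriage-market model.
// All ages and durations are in time steps (10 steps = 1 year).
// Gender coding: 1 = male, 2 = female.

namespace eamsim {

// pow with the convention 0^0 = 1 so a zero weight always neutralises a
// factor (IEEE pow already does this, made explicit here).
inline double wpow(double base, double w) {
  if (w == 0.0) return 1.0;
  return std::pow(base, w);
}

// Mate value v_ij perceived by an observer with education s_i and ideal
// partner age alpha_i in a candidate with education s_j, earnings y_j and
// age a_j. Each factor's base lies in [0, 1]; the age base is clamped at 0.
inline double mate_value(int s_i, int s_j, int y_j, double alpha_i,
                         double a_j, double w_s, double w_y, double w_a,
                         double s_max, double y_max, double a_max) {
  double bs = (s_max - std::abs((double)(s_i - s_j))) / s_max;
  double by = (double)y_j / y_max;
  double ba = (a_max - std::abs(alpha_i - a_j)) / a_max;
  if (ba < 0.0) ba = 0.0;
  return wpow(bs, w_s) * wpow(by, w_y) * wpow(ba, w_a);
}

// Probability that an agent actively searches this step; decays with the
// duration c of the current relationship at commitment rate beta.
inline double seek_probability(double c, double beta) {
  return std::exp(-c * beta);
}

// Probability of being willing to date a candidate with mate value v:
// age pressure builds with own age a, attenuated by commitment to the
// current partner.
inline double date_probability(double a, double v, double c, double sigma,
                               double beta) {
  return (1.0 - std::exp(-a * v * sigma)) * std::exp(-c * beta);
}

// Probability of proposing to / accepting a proposal from the current
// partner; requires both age pressure and accumulated relationship time.
inline double marry_probability(double a, double v, double c, double sigma,
                                double beta) {
  return (1.0 - std::exp(-a * v * sigma)) * (1.0 - std::exp(-c * beta));
}

// Per-step death probability, convex in age; the 0.1 scaling reflects the
// ten steps of a simulation year.
inline double death_probability_step(double a, double d, double w_d,
                                     double a_max) {
  double base = (a_max - std::abs(a_max - a)) / a_max;
  return 0.1 * d * std::pow(base, w_d);
}

// School enrolment as a deterministic function of age (steps) and ultimate
// education. 1 = not yet enrolled, 2 = primary, 3 = secondary,
// 4 = tertiary, 5 = finished.
inline int enrolment_status(double age, int edu) {
  if (age < 60) return 1;
  switch (edu) {
  case 1:
    return 5;
  case 2:
    if (age < 100) return 2;
    if (age < 160) return 3;
    return 5;
  case 3:
    if (age < 100) return 2;
    if (age < 190) return 3;
    return 5;
  default: // tertiary
    if (age < 100) return 2;
    if (age < 190) return 3;
    if (age < 240) return 4;
    return 5;
  }
}

// Ideal partner age. Under the default gendered rule (0) males hold a
// fixed ideal and females prefer partners a fixed offset older than
// themselves; rules 1/2 apply the fixed/offset rule to both genders
// (used for gender-symmetric parameterizations).
inline double ideal_partner_age(int gender, double age, double male_ideal,
                                double female_offset, int rule = 0) {
  if (rule == 1) return male_ideal;
  if (rule == 2) return age + female_offset;
  return gender == 1 ? male_ideal : age + female_offset;
}

} // namespace eamsim

#endif
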