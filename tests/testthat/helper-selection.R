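# Deterministic synthetic regression problem with a known active set
# {tmt_b_minus_a, sigma_mj, sigma_ol} and ~50% explainable variance,
# mimicking the scale of the real predictor battery. Predictor SDs are
# calibrated so the three true terms contribute comparable signal
# (0.10/0.087/0.087 response SD units).
make_selection_table <- function(seed, n = 23) {
  bodyci:::with_seed(seed, {
    tab <- data.frame(
      arm_tactile_2pd = exp(rnorm(n, log(3), 0.25)),
      hand_tactile_2pd = exp(rnorm(n, log(0.7), 0.25)),
      sigma_pj = exp(rnorm(n, log(1), 0.3)),
      sigma_ol = rnorm(n, 5, 4.33),
      sigma_mj = rnorm(n, 4, 0.962),
      digit_span_forward = round(rnorm(n, 5.5, 1)),
      tmt_b_minus_a = rnorm(n)
    )
    signal <- 0.10 * tab$tmt_b_minus_a +
      0.09 * (tab$sigma_mj - mean(tab$sigma_mj)) +
      0.02 * (tab$sigma_ol - mean(tab$sigma_ol))
    tab$ee_arm_length <- 0.12 + signal + rnorm(n, 0, 0.158)
    tab
  })
}
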