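# Independent oracle for the common-cause posterior: brute-force numerical
# integration of the generative model over the 180-degree position range,
# written without reference to the package's closed form.
oracle_pcom <- function(x_v, x_p, sigma_v, sigma_p, p_prior,
                        ds = 0.02, lim = 90) {
  s <- seq(-lim, lim, by = ds)
  w <- rep(ds, length(s)); w[c(1, length(s))] <- ds / 2 # trapezoid
  f_v <- stats::dnorm(x_v, mean = s, sd = sigma_v)
  f_p <- stats::dnorm(x_p, mean = s, sd = sigma_p)
  # one cause: common location s ~ U(-90, 90)
  l1 <- sum(w * (1 / 180) * f_v * f_p)
  # two causes: independent locations, each U(-90, 90)
  l2 <- sum(w * (1 / 180) * f_v) * sum(w * (1 / 180) * f_p)
  p_prior * l1 / (p_prior * l1 + (1 - p_prior) * l2)
}
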