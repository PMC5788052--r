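# shared fixtures, built in code

# a minimal canonical trial table in internal radians
make_trials <- function(target, response, nontargets = NULL,
                        subject = "s01", condition = "retrocue") {
  n <- length(target)
  out <- tibble::tibble(
    subject = subject, experiment = "synthetic", condition = condition,
    control_kind = ifelse(condition == "control", "neutral", "none"),
    set_size = 1L + if (is.null(nontargets)) 0L else ncol(nontargets),
    target = target
  )
  if (!is.null(nontargets)) {
    colnames(nontargets) <- paste0("nontarget_", seq_len(ncol(nontargets)))
    out <- dplyr::bind_cols(out, tibble::as_tibble(nontargets))
  }
  out$response <- response
  out
}

# trapezoidal integral of a function on a fine circular grid
circ_quad <- function(f, n = 20000L) {
  x <- seq(-pi, pi, length.out = n + 1L)[-(n + 1L)]
  sum(f(x)) * 2 * pi / n
}

# modified Bessel I0 by series summation (independent of besselI)
I0_series <- function(x, terms = 60L) {
  k <- 0:terms
  sum((x / 2)^(2 * k) / factorial(k)^2)
}

# two-sided exact signed-rank p by enumeration over all 2^n sign patterns
wilcoxon_enum_p <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  mu <- n * (n + 1) / 4
  mean(abs(v_all - mu) >= abs(v_obs - mu) - 1e-9)
}

# two-sided exact sign-test p by enumeration of binomial outcomes
sign_enum_p <- function(k, n) {
  probs <- dbinom(0:n, n, 0.5)
  min(1, sum(probs[probs <= dbinom(k, n, 0.5) + 1e-12]))
}
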