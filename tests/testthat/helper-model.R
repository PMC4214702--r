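# Shared helpers for the suite: small parameter sets, the spherical Bessel
# j0, and a fine reference quadrature for sphere integrals.

p_il35 <- il35_params("J558-IL-35")
p_ctrl <- il35_params("J558-Ctrl")

j0 <- function(x) ifelse(x == 0, 1, sin(x) / x)

# reference sphere integral of f(r) on [0, R] by composite trapezoid
ref_sphere_integral <- function(f, R, m = 1e4) {
  r <- seq(0, R, length.out = m + 1)
  y <- 4 * pi * r^2 * f(r)
  sum((y[-1] + y[-(m + 1)]) / 2) * (R / m)
}

zero_state <- function() {
  stats::setNames(rep(0, 10), c("c", "q", "M", "rho", "Rg", "beta",
                                "T", "h", "e", "w"))
}

# random nonnegative point state with field-appropriate magnitudes
random_state <- function() {
  mags <- c(c = 0.4, q = 1e-9, M = 1e-2, rho = 1e-10, Rg = 1e-3,
            beta = 1e-10, T = 1e-2, h = 1e-9, e = 5e-3, w = 5e-6)
  stats::setNames(stats::runif(10) * mags, names(mags))
}
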