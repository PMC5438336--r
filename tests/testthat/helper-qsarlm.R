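# shared fixtures built in code

# random regression instance with a linear signal
rand_instance <- function(n = 19, k = 3, noise_sd = 0.5, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * k), n, k,
              dimnames = list(sprintf("c%02d", seq_len(n)), paste0("V", seq_len(k))))
  beta <- seq_len(k)
  y <- as.numeric(5 + x %*% beta + rnorm(n, sd = noise_sd))
  list(x = x, y = y, beta = beta, intercept = 5)
}

# two columns with an exact given sample correlation
corr_pair <- function(n = 20, r = 0.9, seed = 1) {
  set.seed(seed)
  a <- rnorm(n)
  b0 <- rnorm(n)
  a <- as.numeric(scale(a))
  b0 <- residuals(lm(b0 ~ a))
  b0 <- as.numeric(scale(b0))
  cbind(a = a, b = r * a + sqrt(1 - r^2) * b0)
}

# write a small descriptor CSV and return its path
write_desc_csv <- function(df) {
  path <- tempfile("desc", fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  path
}
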