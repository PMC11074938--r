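# fixture builders shared across test files; everything is generated in code

# tiny hand-rolled observation table: n animals per group, given days
toy_table <- function(n_per_group = 4, days = c(2, 4), seed = 1,
                      splx_shift = 0) {
  set.seed(seed)
  ids <- c(sprintf("sx%02d", seq_len(n_per_group)),
           sprintf("sh%02d", seq_len(n_per_group)))
  grp <- rep(c("SPLX", "SPL-sham"), each = n_per_group)
  out <- expand.grid(animal_id = ids, day = days, stringsAsFactors = FALSE)
  out$group <- grp[match(out$animal_id, ids)]
  base <- ifelse(out$group == "SPLX", splx_shift, 0)
  out$mass <- 25 + base + rnorm(nrow(out))
  out$ns <- pmin(pmax(round(12 + base + rnorm(nrow(out))), 3), 18)
  out$mr_il <- 230 + base + rnorm(nrow(out), sd = 5)
  out$mr_cl <- 225 + rnorm(nrow(out), sd = 5)
  out$bli_flux <- exp(rnorm(nrow(out), log(1e6), 0.3))
  out$bli_radiance <- exp(rnorm(nrow(out), log(5e4), 0.3))
  out[c("animal_id", "group", "day", "mass", "ns", "mr_il", "mr_cl",
        "bli_flux", "bli_radiance")]
}

# two-feature, strongly separable toy classification table (one row per animal)
separable_table <- function(n_per_group = 60, separation = 10, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_group
  out <- data.frame(
    animal_id = sprintf("a%03d", seq_len(n)),
    group = rep(c("SPLX", "SPL-sham"), each = n_per_group),
    day = 2,
    stringsAsFactors = FALSE)
  out$mass <- rnorm(n, ifelse(out$group == "SPLX", separation, 0), 1)
  out$ns <- 10
  out$mr_il <- rnorm(n, ifelse(out$group == "SPLX", 0, separation), 1) + 100
  out$mr_cl <- 100
  out$bli_flux <- 1e5
  out$bli_radiance <- 1e4
  attr(out, "features") <- c("mass", "mr_il")
  out
}

tiny_spec <- function(input_dim = 2L, epochs = 60L, patience = 0L) {
  network_spec(input_dim = input_dim, hidden_widths = rep(8L, 7),
               epochs = epochs, patience = patience)
}

# brute-force one-way ANOVA from sums of squares (independent oracle)
oracle_anova <- function(groups) {
  y <- unlist(groups)
  gm <- mean(y)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, 0))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  df1 <- length(groups) - 1
  df2 <- length(y) - length(groups)
  F <- (ssb / df1) / (ssw / df2)
  list(F = F, df = c(df1, df2),
       p = pf(F, df1, df2, lower.tail = FALSE))
}
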