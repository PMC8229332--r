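test_that("band power is mean squared amplitude: sinusoid, zero and Parseval checks", {
  fs <- 256
  x <- sin(2 * pi * 10 * (0:(fs - 1)) / fs)
  data <- array(0, c(2, fs, 1))
  data[1, , 1] <- x
  es <- make_epochset(data, "fear", fs = fs)
  pw <- band_power(es)
  expect_equal(pw[1, 1], 0.5, tolerance = 1e-10)   # unit sinusoid -> 1/2
  expect_equal(pw[1, 2], 0)
  # white noise: time-domain power equals the periodogram integral (Parseval)
  set.seed(1)
  w <- rnorm(fs)
  esw <- make_epochset(array(w, c(1, fs, 1)), "fear", fs = fs)
  sp <- spec.pgram(ts(w, frequency = fs), plot = FALSE, taper = 0,
                   detrend = FALSE)
  pgram_power <- 2 * sum(sp$spec) * diff(sp$freq[1:2])
  expect_equal(band_power(esw)[1, 1], pgram_power,
               tolerance = 0.01)
})

test_that("percent change arithmetic and scale invariance", {
  expect_equal(percent_change(1, 1), 0)
  expect_equal(percent_change(1.35, 1), 35, tolerance = 1e-12)
  expect_equal(percent_change(0.5, 1), -50)
  expect_error(percent_change(1, 0), "positive")
  # ratio statistic: global amplitude scaling cancels
  s <- runif(5) + 0.5; b <- runif(5) + 0.5
  expect_equal(percent_change(9 * s, 9 * b), percent_change(s, b),
               tolerance = 1e-12)
})

test_that("planted sources raise band power in the effect band only, during activity only", {
  g <- quick_epochs("PI", trials_per_state = 3, snr = 10,
                    band_of_effect = c(9, 12), seed = 41)
  fb <- bandpass_filterbank(g$epochs,
                            filter_bank_spec(list(alpha = c(8, 13),
                                                  high_gamma = c(51, 70))))
  tab <- band_power_table(fb, subject = 1, paradigm = "PI")
  reg <- region_average(tab)
  alpha_chg <- mean(reg$percent_change[reg$band == "alpha"])
  gamma_chg <- mean(reg$percent_change[reg$band == "high_gamma"])
  expect_gt(alpha_chg, 100)          # strong synchronization in-band
  expect_lt(abs(gamma_chg), 50)      # near zero out of band
})

test_that("region averages equal the mean of their member channels", {
  g <- quick_epochs("PI", trials_per_state = 2, snr = 2, seed = 42)
  fb <- bandpass_filterbank(g$epochs,
                            filter_bank_spec(list(alpha = c(8, 13))))
  tab <- band_power_table(fb, subject = 1, paradigm = "PI")
  reg <- region_average(tab)
  mon <- emotiv_montage()
  for (r in unique(reg$region)) {
    chans <- names(mon$regions)[mon$regions == r]
    for (s in unique(tab$state)) {
      direct <- mean(tab$percent_change[tab$state == s & tab$channel %in% chans])
      expect_equal(reg$percent_change[reg$region == r & reg$state == s],
                   direct, tolerance = 1e-10)
    }
  }
})

test_that("identical fear and joy values give F = 0, p = 1 for the state effect", {
  tab <- simulate_bandpower_table(4, seed = 3)
  wide <- tab[tab$state == "fear", ]
  dup <- rbind(wide, transform(wide, state = "joy"))
  res <- rm_anova(dup, c("state", "band", "region"))
  st <- res[res$effect == "state", ]
  expect_equal(st$F, 0, tolerance = 1e-10)
  expect_equal(st$p, 1, tolerance = 1e-10)
})

test_that("two-level single-factor repeated-measures F equals the squared paired t", {
  set.seed(4)
  n <- 9
  tab <- data.frame(subject = rep(1:n, 2),
                    state = rep(c("fear", "joy"), each = n),
                    percent_change = rnorm(2 * n, sd = 5) +
                      rep(c(0, 2), each = n))
  res <- rm_anova(tab, "state")
  a <- tab$percent_change[tab$state == "fear"]
  b <- tab$percent_change[tab$state == "joy"]
  tt <- t.test(a, b, paired = TRUE)
  expect_equal(res$F[res$effect == "state"], unname(tt$statistic)^2,
               tolerance = 1e-10)
  expect_equal(res$p[res$effect == "state"], tt$p.value, tolerance = 1e-10)
})

test_that("a planted state effect is detected in the right (band, region) cell", {
  hits <- 0
  for (i in 1:25) {
    # planted shift of 3 residual sd: a clearly separated effect
    tab <- simulate_bandpower_table(8, effect = 30,
                                    effect_cell = c("beta", "Pa"),
                                    seed = 500 + i)
    ct <- state_contrasts(tab)
    top <- ct[which.min(ct$p), ]
    if (top$band == "beta" && top$region == "Pa") hits <- hits + 1
  }
  expect_gte(hits, 23)   # >= 90% localization
})

test_that("ANOVA requires at least 3 complete subjects and drops incomplete ones", {
  tab <- simulate_bandpower_table(2, seed = 1)
  expect_error(rm_anova(tab), "3 complete subjects")
  tab4 <- simulate_bandpower_table(4, seed = 2)
  broken <- tab4[!(tab4$subject == 4 & tab4$band == "alpha"), ]
  expect_message(res <- rm_anova(broken), "incomplete subject")
  expect_true(all(is.finite(res$F)))
})

test_that("topographic export: round trip, montage consistency, planted channels dominate", {
  mon <- emotiv_montage()
  g <- quick_epochs("PI", trials_per_state = 2, snr = 2, seed = 44)
  fb <- bandpass_filterbank(g$epochs,
                            filter_bank_spec(list(alpha = c(8, 13))))
  tab <- band_power_table(fb, subject = 1, paradigm = "PI")
  topo <- topographic_export(tab, mon, state = "fear")
  expect_equal(nrow(topo), 14)
  expect_equal(topo$channel, mon$channels)
  f <- tempfile(fileext = ".tsv")
  write.table(topo, f, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read.table(f, header = TRUE, sep = "\t")
  expect_equal(back$value, topo$value, tolerance = 1e-12)

  # a CSP pattern planted on two channels exports those channels on top
  pat <- rep(0.05, 14); pat[3] <- 1; pat[12] <- -0.9   # F3, F4
  P <- diag(14); P[, 3] <- pat
  mod <- structure(list(projection = diag(14), patterns = P,
                        eigvals_class1 = rep(0.5, 14), m = 1,
                        selected = c(1L, 14L), band = "broadband"),
                   class = "csp_model")
  tp <- topographic_export(mod, mon, pattern = 3)
  top2 <- tp$channel[order(abs(tp$value), decreasing = TRUE)][1:2]
  expect_setequal(top2, c("F3", "F4"))
  # unknown channels are refused
  bad <- tab; bad$channel[1] <- "XX9"
  expect_error(topographic_export(bad, mon, state = "fear"), "XX9")
})
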