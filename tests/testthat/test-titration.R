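test_that("single uncoupled sites reproduce the closed form", {
  grid <- seq(0, 14, by = 0.25)
  for (g in c("ASP", "HIS", "LYS")) {
    sys <- make_system(g, unname(default_model_pkas()[g]))
    cur <- enumerate_titration(sys, grid)
    want <- closed_form_ionisation(sys$pka_int, sys$gamma, grid)
    expect_equal(cur$ionisation, want, tolerance = 1e-12)
    pk <- pka_from_curve(cur)
    expect_false(pk$censored)
    expect_equal(pk$apparent_pka, sys$pka_int, tolerance = 0.01)
  }
  # histidine titrates at its non-perturbed pKa of 6.3
  sys <- make_system("HIS", 6.3)
  cur <- enumerate_titration(sys, grid)
  expect_equal(pka_from_curve(cur)$apparent_pka, 6.3, tolerance = 0.01)
  # half-ionisation exactly on-grid for a pKa 4.0 acid
  sysA <- make_system("ASP", 4.0)
  curA <- enumerate_titration(sysA, grid)
  expect_equal(curA$ionisation[curA$ph == 4.0], 0.5)
})

test_that("two identical repulsively coupled acids split their stepwise
           pKas by ~2 units and match a 4-microstate oracle", {
  W <- matrix(c(0, 11.5, 11.5, 0), 2)
  sys <- make_system(c("ASP", "ASP"), c(4, 4), W)
  grid <- seq(0, 14, by = 0.05)
  cur <- enumerate_titration(sys, grid)
  # per-site curves match the brute-force microstate average
  for (ph in c(3, 4, 5, 6, 7)) {
    want <- brute_titration(sys, ph)
    got <- cur$ionisation[cur$ph == ph]
    expect_equal(got, unname(want), tolerance = 1e-9)
  }
  # stepwise (total-charge) pKas: pH at total ionisation 0.5 and 1.5
  tot <- cur |>
    dplyr::group_by(ph) |>
    dplyr::summarise(tot = sum(ionisation))
  ph_at <- function(level) {
    k <- which(tot$tot >= level)[1]
    tot$ph[k]
  }
  # ~2 units of coupling plus the log10(4) statistical-factor split
  split <- ph_at(1.5) - ph_at(0.5)
  expect_gt(split, 1.9)
  expect_lt(split, 3.0)
})

test_that("enumeration rejects oversized systems and short grids", {
  sys <- make_system(rep("ASP", 21), rep(4, 21))
  expect_error(enumerate_titration(sys), "mc_titration")
  sys1 <- make_system("ASP", 4)
  cur <- enumerate_titration(sys1, c(4.0))
  expect_error(pka_from_curve(cur), ">= 2")
})

test_that("Monte Carlo matches enumeration within 0.05 pKa units", {
  set.seed(99)
  systems <- list(
    make_system(c("ASP", "LYS"), c(6, 8.5),
                matrix(c(0, -15, -15, 0), 2)),
    make_system(c("ASP", "ASP", "LYS"), c(5.5, 5.5, 9),
                matrix(c(0, 12, -18, 12, 0, -18, -18, -18, 0), 3)),
    make_system(rep(c("ASP", "HIS", "LYS"), 4),
                rep(c(4.5, 6.0, 9.5), 4),
                {
                  W <- matrix(0, 12, 12)
                  W[1, 2] <- W[2, 1] <- -13
                  W[4, 5] <- W[5, 4] <- -12
                  W[7, 8] <- W[8, 7] <- 14
                  W
                })
  )
  for (sys in systems) {
    pe <- pka_from_curve(enumerate_titration(sys))
    pm <- pka_from_curve(mc_titration(sys, seed = 11))
    ok <- !pe$censored & !pm$censored
    expect_true(any(ok))
    expect_lt(max(abs(pe$apparent_pka[ok] - pm$apparent_pka[ok])), 0.05)
  }
})

test_that("an uncoupled 30-site system matches the closed form and the
           sampler is deterministic under a seed", {
  groups <- rep(c("ASP", "GLU", "HIS", "LYS", "ARG"), 6)
  pkas <- unname(default_model_pkas()[groups]) +
    rep(c(-0.5, 0, 0.5), 10)
  sys <- make_system(groups, pkas)
  grid <- seq(0, 14, by = 0.5)
  cm <- mc_titration(sys, grid, seed = 5)
  want <- unlist(lapply(seq_along(groups), function(i) {
    closed_form_ionisation(pkas[i], sys$gamma[i], grid)
  }))
  expect_lt(max(abs(cm$ionisation - want)), 0.02)
  cm2 <- mc_titration(sys, grid, seed = 5)
  expect_identical(cm$ionisation, cm2$ionisation)
  expect_error(mc_titration(sys, grid, n_sweeps = 10), "1000")
})

test_that("apparent pKa interpolates linearly and censors at boundaries", {
  # synthetic curve crossing 0.5 between 4.0 (0.45) and 4.2 (0.55)
  cur <- tibble::tibble(site_id = "s1", ph = c(3.8, 4.0, 4.2, 4.4),
                        ionisation = c(0.3, 0.45, 0.55, 0.7))
  class(cur) <- c("titration_curves", class(cur))
  expect_equal(pka_from_curve(cur)$apparent_pka, 4.1, tolerance = 1e-9)
  # monotone curve never reaching 0.5: censored at the near boundary
  low <- tibble::tibble(site_id = "s1", ph = seq(0, 14, 1),
                        ionisation = seq(0.01, 0.4,
                                         length.out = 15))
  class(low) <- c("titration_curves", class(low))
  pk <- pka_from_curve(low)
  expect_true(pk$censored)
  expect_equal(pk$apparent_pka, 14)
  # closed-form curve for pKa 7.25 on a 0.25 grid interpolates to 7.25
  sys <- make_system("HIS", 7.25)
  pk2 <- pka_from_curve(enumerate_titration(sys, seq(0, 14, 0.25)))
  expect_equal(pk2$apparent_pka, 7.25, tolerance = 0.01)
})

test_that("delta Q vanishes for unperturbed sites and matches closed-form
           arithmetic for shifted ones", {
  sys <- make_system("ASP", 4.0)
  cur <- enumerate_titration(sys)
  dq <- delta_q_at_ph(cur, 7)
  expect_equal(dq$delta_q, 0, tolerance = 1e-12)
  # buried HIS, intrinsic 4.21: |prot(7; 4.21) - prot(7; 6.3)| ~ 0.165
  sysh <- make_system("HIS", 4.21)
  dqh <- delta_q_at_ph(enumerate_titration(sysh), 7)
  expect_equal(dqh$delta_q,
               abs(1 / (1 + 10^(7 - 4.21)) - 1 / (1 + 10^(7 - 6.3))),
               tolerance = 1e-9)
  # shift of +2 evaluated at the model pKa
  sysa <- make_system("ASP", 6.0)
  dqa <- delta_q_at_ph(enumerate_titration(sysa), 4.0)
  expect_equal(dqa$delta_q, abs(1 / (1 + 10^(4 - 6)) - 0.5),
               tolerance = 1e-9)
  expect_error(delta_q_at_ph(enumerate_titration(sysa), 7.123),
               "grid")
})

test_that("uncoupled and pairwise-repulsive curves are monotone in pH", {
  set.seed(31)
  # zero couplings: every site monotone, any mixture of groups
  for (rep in 1:3) {
    n <- sample(3:6, 1)
    groups <- sample(c("ASP", "GLU", "HIS", "LYS"), n, replace = TRUE)
    pkas <- unname(default_model_pkas()[groups]) + stats::rnorm(n, 0, 1.5)
    sys <- make_system(groups, pkas)
    cur <- enumerate_titration(sys, seq(0, 14, 0.5))
    for (sid in unique(cur$site_id)) {
      y <- cur$ionisation[cur$site_id == sid]
      g <- sys$gamma[match(sid, sys$site_id)]
      expect_true(all(diff(y) * (-g) >= -1e-9))
    }
  }
  # repulsively coupled like-charge pairs: monotone
  for (rep in 1:3) {
    grp <- sample(list(c("ASP", "GLU"), c("LYS", "HIS")), 1)[[1]]
    pkas <- unname(default_model_pkas()[grp]) + stats::rnorm(2, 0, 1.5)
    W <- matrix(c(0, 1, 1, 0), 2) * stats::runif(1, 5, 25)
    sys <- make_system(grp, pkas, W)
    cur <- enumerate_titration(sys, seq(0, 14, 0.25))
    for (sid in unique(cur$site_id)) {
      y <- cur$ionisation[cur$site_id == sid]
      g <- sys$gamma[match(sid, sys$site_id)]
      expect_true(all(diff(y) * (-g) >= -1e-9))
    }
  }
})

test_that("total protonation never increases with pH for any couplings", {
  set.seed(32)
  for (rep in 1:5) {
    n <- sample(2:5, 1)
    groups <- sample(c("ASP", "GLU", "HIS", "LYS"), n, replace = TRUE)
    pkas <- unname(default_model_pkas()[groups]) + stats::rnorm(n, 0, 1)
    W <- matrix(0, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (stats::runif(1) < 0.5) {
        W[i, j] <- W[j, i] <- stats::runif(1, -25, 25)
      }
    }
    sys <- make_system(groups, pkas, W)
    cur <- enumerate_titration(sys, seq(0, 14, 0.5))
    gam <- sys$gamma
    prot <- cur |>
      dplyr::mutate(g = gam[match(site_id, sys$site_id)],
                    prot = ifelse(g < 0, 1 - ionisation, ionisation)) |>
      dplyr::group_by(ph) |>
      dplyr::summarise(total = sum(prot))
    expect_true(all(diff(prot$total) <= 1e-9))
  }
})

test_that("tidy and glance summarise titration runs", {
  sys <- make_system(c("ASP", "HIS"), c(4, 6.3))
  cur <- enumerate_titration(sys)
  td <- tidy(cur, ph = 7)
  expect_named(td, c("site_id", "apparent_pka", "censored", "delta_q"))
  expect_equal(nrow(td), 2)
  gl <- glance(cur)
  expect_equal(gl$n_sites, 2)
  expect_equal(gl$engine, "enumerate")
})
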