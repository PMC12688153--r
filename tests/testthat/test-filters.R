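range_sites <- function() {
  tibble::tibble(
    site_id = paste0("s", 1:4), chain = "A", resnum = 1:4,
    group = c("HIS", "ASP", "LYS", "CYS"),
    moiety_sasa = c(2, 20.8, 0, 1),
    pka_emp = c(6.3, 6.0, 10.4, 7.0),
    apparent_pka = c(6.3, 6.0, 10.4, 7.0),
    censored = FALSE,
    delta_q = c(0.3, 0.25, 0.01, 0.5)
  )
}

test_that("the pKa-range filter applies both the window and burial", {
  s <- range_sites()
  got <- pka_range_filter(s, "pka_emp", sasa_max = 15)
  # HIS in range and buried: in; ASP in range but SASA 20.8: out;
  # LYS buried but pKa 10.4: out; CYS never assessed
  expect_equal(got$group, "HIS")
  # censored titration pKas are excluded
  s$censored <- c(TRUE, FALSE, FALSE, FALSE)
  got2 <- pka_range_filter(s, "apparent_pka", sasa_max = 15)
  expect_equal(nrow(got2), 0)
})

test_that("the network filter returns the union of DEKRH members", {
  toy <- toy_fixture()
  an <- toy$analysis
  nets <- charge_networks(an$graph, an$sites, list(sasa_max = 15), 3)
  got <- network_filter(nets, an$sites)
  expect_equal(nrow(got), 3)
  expect_setequal(got$resnum, toy$manifest$resnum[
    toy$manifest$burial_class == "buried"])
  # two disjoint qualifying dyads under min_dekrh = 2 give 4 residues
  ids <- paste0("s", 1:4)
  W <- matrix(0, 4, 4, dimnames = list(ids, ids))
  W[1, 2] <- W[2, 1] <- -15; W[3, 4] <- W[4, 3] <- 15
  g <- coupling_graph(structure(list(site_id = ids, W = W),
                                class = "interaction_matrix"))
  sites <- tibble::tibble(site_id = ids, chain = "A", resnum = 1:4,
                          group = c("ASP", "LYS", "GLU", "GLU"),
                          moiety_sasa = 0)
  nets2 <- charge_networks(g, sites, list(sasa_max = 5), 2)
  expect_equal(nrow(network_filter(nets2, sites)), 4)
  # empty networks: empty residue list
  expect_equal(nrow(network_filter(nets2[0, ], sites)), 0)
})

test_that("intersections demand both components and merge residues", {
  r1 <- tibble::tibble(chain = "A", resnum = 1L, group = "HIS")
  n1 <- tibble::tibble(chain = "A", resnum = 2L, group = "ASP")
  both <- intersection_filter(r1, n1, 15, 15)
  expect_true(both$pass)
  expect_equal(nrow(both$bcoi), 2)
  onlyr <- intersection_filter(r1, n1[0, ], 15, 15)
  expect_false(onlyr$pass)
  expect_equal(nrow(onlyr$bcoi), 0)
  expect_error(intersection_filter(r1, n1, 15, 5), "mismatched")
})

test_that("the delta-Q filter enforces burial, the threshold and the
           histidine pKa floor", {
  s <- range_sites()
  got <- deltaq_filter(s, sasa_max = 10, dq_min = 0.2)
  expect_setequal(got$group, "HIS")  # ASP fails SASA, LYS dq, CYS group
  # exposed ASP with delta Q 0 stays out even at generous burial
  s2 <- s; s2$moiety_sasa <- 1; s2$delta_q[2] <- 0
  expect_false("ASP" %in% deltaq_filter(s2)$group)
  # a buried His with dq 0.25 but pKa 4.2 is excluded by the floor
  s3 <- s; s3$delta_q[1] <- 0.25; s3$apparent_pka[1] <- 4.2
  expect_false("HIS" %in% deltaq_filter(s3)$group)
  # buried ASP with compensating partner: dq 0.3, SASA 1 -> included
  s4 <- s; s4$moiety_sasa[2] <- 1; s4$delta_q[2] <- 0.3
  expect_true("ASP" %in% deltaq_filter(s4)$group)
})

test_that("a deeply buried acid pair triggers the delta-Q filter through
           the titration engine", {
  toy <- make_toy_protomer(list(buried_cluster(c("ASP", "ASP"), 7)),
                           protein_id = "dyad")
  an <- analyze_protomer(toy$model)
  expect_gte(max(an$sites$delta_q), 0.2)
  suite <- run_filter_suite(an)
  expect_true(suite$pass[suite$filter == "pkcalc-deltaQ-10"])
})

test_that("the canonical suite has the ten filters in order and obeys
           set relations on the planted fixture", {
  toy <- toy_fixture()
  suite <- toy$suite
  expect_equal(suite$filter, canonical_filters()$name)
  expect_equal(nrow(suite), 10)
  wide <- filter_results_wide(suite)
  expect_equal(names(wide)[2:11], canonical_filters()$name)
  # intersection pass implies both components pass
  p <- function(f) suite$pass[suite$filter == f]
  expect_true(p("pkcalc-15-3-propka-15") <=
                (p("pkcalc-int-15-3") && p("propka-range-15")))
  expect_true(p("pkcalc-5-2-propka-5") <=
                (p("pkcalc-int-5-2") && p("propka-range-5")))
  # every reported residue respects its filter's burial threshold
  spec <- canonical_filters()
  sasa <- toy$analysis$sites
  for (k in seq_len(nrow(spec))) {
    b <- suite$bcoi[[k]]
    if (nrow(b) == 0) next
    ms <- sasa$moiety_sasa[match(paste(b$chain, b$resnum),
                                 paste(sasa$chain, sasa$resnum))]
    if (!is.na(spec$sasa_max[k])) {
      expect_true(all(ms <= spec$sasa_max[k]))
    } else {
      expect_true(all(!sasa$dh_access[match(
        paste(b$chain, b$resnum), paste(sasa$chain, sasa$resnum))]))
    }
    expect_true(all(b$group %in% c("ASP", "GLU", "LYS", "ARG", "HIS")))
  }
  # pass <=> non-empty residue list
  expect_equal(suite$pass, vapply(suite$bcoi, nrow, 1L) > 0)
})

test_that("relaxing the SASA threshold never removes passes", {
  toy <- toy_fixture()
  an <- toy$analysis
  n5 <- charge_networks(an$graph, an$sites, list(sasa_max = 5), 2)
  n15 <- charge_networks(an$graph, an$sites, list(sasa_max = 15), 2)
  r5 <- network_filter(n5, an$sites)
  r15 <- network_filter(n15, an$sites)
  expect_true(all(paste(r5$chain, r5$resnum) %in%
                    paste(r15$chain, r15$resnum)))
  p5 <- pka_range_filter(an$sites, "pka_emp", 5)
  p15 <- pka_range_filter(an$sites, "pka_emp", 15)
  expect_true(all(paste(p5$chain, p5$resnum) %in%
                    paste(p15$chain, p15$resnum)))
})

test_that("a protein with no buried groups fails all ten filters", {
  toy <- make_toy_protomer(list(surface_singleton("LYS"),
                                surface_singleton("ASP")),
                           protein_id = "allsurf")
  suite <- run_filter_suite(analyze_protomer(toy$model))
  expect_false(any(suite$pass))
  gl <- glance(suite)
  expect_equal(gl$n_pass, 0)
  expect_equal(gl$n_bcoi_residues, 0)
})

test_that("missing engine output is reported with the filter name", {
  toy <- toy_fixture()
  an <- toy$analysis
  an$sites$delta_q <- NULL
  expect_error(run_filter_suite(an), "pkcalc-deltaQ-10")
})
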