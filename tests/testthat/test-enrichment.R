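test_that("subset algebra matches inclusion-exclusion", {
  labels <- tibble::tibble(
    protein_id = paste0("p", 1:5),
    enzyme = c(1, 1, 1, 0, 0),
    transporter = c(0, 0, 0, 1, 1)
  )
  got <- subset_algebra(labels)
  expect_equal(got$n_et, 5)
  expect_equal(got$n_net, 0)
  # random tables against a brute-force set oracle
  set.seed(12)
  for (rep in 1:5) {
    n <- 200
    lab <- tibble::tibble(
      protein_id = paste0("p", 1:n),
      enzyme = stats::rbinom(n, 1, 0.3),
      transporter = stats::rbinom(n, 1, 0.1),
      ph_dependent = stats::rbinom(n, 1, 0.05)
    )
    got <- subset_algebra(lab)
    eset <- lab$protein_id[lab$enzyme == 1]
    tset <- lab$protein_id[lab$transporter == 1]
    expect_equal(got$n_et, length(union(eset, tset)))
    expect_equal(got$n_both, length(intersect(eset, tset)))
    expect_equal(got$n_net, n - length(union(eset, tset)))
    expect_equal(got$n_et, got$n_enzyme + got$n_transporter - got$n_both)
  }
  expect_error(subset_algebra(dplyr::bind_rows(labels, labels[1, ])),
               "duplicate")
})

test_that("enrichment ratios follow the defining arithmetic", {
  expect_equal(enrichment_ratio(20, 100, 50, 1000)$ratio, 4.0)
  expect_equal(enrichment_ratio(5, 50, 100, 1000)$ratio, 1.0)
  # scale invariance
  r1 <- enrichment_ratio(20, 100, 50, 1000)$ratio
  r2 <- enrichment_ratio(60, 300, 150, 3000)$ratio
  expect_equal(r1, r2)
  expect_true(enrichment_ratio(5, 50, 0, 1000)$censored)
  expect_error(enrichment_ratio(5, 0, 10, 100), "positive")
})

test_that("a planted 3x pass-rate enrichment is recovered", {
  co <- make_cohort(n_proteins = 5000, pass_prob_et = 0.3,
                    pass_prob_net = 0.1, seed = 424)
  counts <- subset_algebra(co$labels)
  et <- co$labels$protein_id[co$labels$enzyme == 1 |
                               co$labels$transporter == 1]
  f1 <- co$passes[co$passes$filter == canonical_filters()$name[1], ]
  r <- enrichment_ratio(
    sum(f1$pass & f1$protein_id %in% et), counts$n_et,
    sum(f1$pass & !f1$protein_id %in% et), counts$n_net
  )
  expect_gt(r$ratio, 2.5)
  expect_lt(r$ratio, 3.5)
})

test_that("ROC rates recover planted class-conditional pass rates", {
  co <- make_cohort(n_proteins = 2000, pass_prob_et = 0.8,
                    pass_prob_net = 0.2, seed = 77)
  f1 <- co$passes[co$passes$filter == canonical_filters()$name[1],
                  c("protein_id", "pass")]
  roc <- roc_scan(f1, co$labels)
  expect_gt(roc$tpr, 0.75); expect_lt(roc$tpr, 0.85)
  expect_gt(roc$fpr, 0.15); expect_lt(roc$fpr, 0.25)
  # degenerate classifiers
  lab <- co$labels
  et <- lab$protein_id[lab$enzyme == 1 | lab$transporter == 1]
  perfect <- tibble::tibble(protein_id = lab$protein_id,
                            pass = lab$protein_id %in% et)
  expect_equal(unlist(roc_scan(perfect, lab)), c(tpr = 1, fpr = 0))
  all_pass <- tibble::tibble(protein_id = lab$protein_id, pass = TRUE)
  expect_equal(unlist(roc_scan(all_pass, lab)), c(tpr = 1, fpr = 1))
  only_et <- lab; only_et$transporter <- 1; only_et$enzyme <- 1
  expect_error(roc_scan(perfect, only_et), "non-empty")
})

test_that("ROC points are nested as the delta-Q cut relaxes", {
  set.seed(5)
  n <- 500
  dq <- stats::runif(n)
  lab <- tibble::tibble(protein_id = paste0("p", 1:n),
                        enzyme = stats::rbinom(n, 1, 0.3),
                        transporter = 0)
  grid <- tidyr::expand_grid(protein_id = paste0("p", 1:n),
                             dq_min = seq(0, 1, 0.1)) |>
    dplyr::mutate(pass = dq[match(protein_id,
                                  paste0("p", 1:n))] >= dq_min)
  roc <- roc_scan(grid, lab) |> dplyr::arrange(dplyr::desc(dq_min))
  expect_true(all(diff(roc$tpr) >= 0))
  expect_true(all(diff(roc$fpr) >= 0))
  expect_true(all(roc$tpr >= 0 & roc$tpr <= 1))
})

test_that("filter overlap ratios follow the observed/expected algebra", {
  ids <- paste0("p", 1:100)
  res <- dplyr::bind_rows(
    tibble::tibble(protein_id = ids, filter = "A",
                   pass = ids %in% ids[1:20]),
    tibble::tibble(protein_id = ids, filter = "B",
                   pass = ids %in% ids[1:20]),
    tibble::tibble(protein_id = ids, filter = "C",
                   pass = ids %in% ids[21:40]),
    tibble::tibble(protein_id = ids, filter = "D", pass = FALSE)
  )
  ov <- filter_overlap_matrix(res, n_total = 100)
  pick <- function(i, j) ov$ratio[ov$filter_i == i & ov$filter_j == j]
  expect_equal(pick("A", "B"), 100 / 20)   # identical filters: N/k
  expect_equal(pick("A", "C"), 0)          # disjoint filters
  expect_true(is.na(pick("A", "D")))       # empty filter: censored
})

test_that("independent random pass sets give overlap ratios near 1", {
  co <- make_cohort(n_proteins = 10000, pass_prob_et = 0.3,
                    pass_prob_net = 0.3,
                    filters = c("f1", "f2", "f3"), seed = 99)
  ov <- filter_overlap_matrix(co$passes, n_total = 10000)
  expect_true(all(ov$ratio > 0.8 & ov$ratio < 1.2))
})

test_that("GO annotations propagate along the hierarchy and cycles are
           rejected", {
  ann <- tibble::tibble(protein_id = "p1", term_id = "leaf")
  hier <- tibble::tibble(term_id = c("leaf", "mid"),
                         parent_id = c("mid", "root"))
  got <- propagate_annotations(ann, hier)
  expect_setequal(got$term_id, c("leaf", "mid", "root"))
  cyc <- tibble::tibble(term_id = c("a", "b"), parent_id = c("b", "a"))
  expect_error(propagate_annotations(ann, cyc), "cycle")
})

test_that("fold enrichment is 1 when query equals reference and recovers a
           planted fold", {
  ann <- tibble::tibble(protein_id = rep(paste0("p", 1:50), 2),
                        term_id = rep(c("t1", "t2"), each = 50))
  hier <- tibble::tibble(term_id = c("t1", "t2"), parent_id = "root")
  ids <- paste0("p", 1:50)
  same <- go_fold_enrichment(ids, ids, ann, hier)
  expect_true(all(same$fold == 1))
  co <- make_cohort(n_proteins = 2000, seed = 31)
  folds <- go_fold_enrichment(co$query, co$labels$protein_id,
                              co$annotations, co$hierarchy)
  planted <- folds$fold[folds$term_id == "GO:PLANT1"]
  expect_gt(planted, 2.4)
  expect_lt(planted, 3.6)
  nulls <- folds$fold[folds$term_id %in% c("GO:NULL1", "GO:NULL2")]
  expect_true(all(abs(nulls - 1) < 0.25))
  expect_error(
    go_fold_enrichment(c(ids, "stranger"), ids, ann, hier),
    "subset"
  )
})

test_that("uniform annotation probabilities concentrate folds at 1", {
  co <- make_cohort(
    n_proteins = 5000,
    go_terms = tibble::tibble(term_id = paste0("GO:U", 1:5),
                              base_prob = 0.15, fold = 1),
    seed = 8
  )
  folds <- go_fold_enrichment(co$query, co$labels$protein_id,
                              co$annotations, co$hierarchy)
  leaf <- folds[folds$term_id != "GO:ROOT", ]
  expect_lt(abs(mean(leaf$fold) - 1), 0.1)
})

test_that("a basis term list pins the output and censors absent terms", {
  ann <- tibble::tibble(protein_id = c("p1", "p2"),
                        term_id = c("t1", "t1"))
  hier <- tibble::tibble(term_id = "t1", parent_id = "root")
  got <- go_fold_enrichment("p1", c("p1", "p2"), ann, hier,
                            basis = c("t1", "root", "absent"))
  expect_equal(got$term_id, c("t1", "root", "absent"))
  expect_true(got$censored[got$term_id == "absent"])
  basis <- go_basis_terms(c("p1"), ann, hier)
  expect_setequal(basis, c("t1", "root"))
})
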