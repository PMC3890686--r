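# Toy database: two species, distances hand-chosen per scenario.
toy_labels <- c(q = "sp_x", c1 = "sp_x", c2 = "sp_x", h1 = "sp_y", h2 = "sp_y")

toy_ident_dm <- function(dq) {
  ids <- names(toy_labels)
  d <- matrix(0.2, 5, 5, dimnames = list(ids, ids))
  diag(d) <- 0
  d["q", names(dq)] <- d[names(dq), "q"] <- dq
  make_dm(d, ids)
}

test_that("best close match scores all four outcomes correctly", {
  # nearest conspecific within threshold -> correct
  dm <- toy_ident_dm(c(c1 = 0.01, c2 = 0.03, h1 = 0.1, h2 = 0.1))
  r <- best_close_match("q", dm, toy_labels, threshold = 0.047)
  expect_equal(r$outcome, "correct")
  expect_equal(r$matched_ids, "c1")

  # nearest beyond threshold -> no_id with empty support
  dm <- toy_ident_dm(c(c1 = 0.06, c2 = 0.07, h1 = 0.1, h2 = 0.1))
  r <- best_close_match("q", dm, toy_labels, threshold = 0.047)
  expect_equal(r$outcome, "no_id")
  expect_equal(r$matched_ids, "")

  # conspecific and heterospecific tied for closest -> ambiguous
  dm <- toy_ident_dm(c(c1 = 0.01, c2 = 0.05, h1 = 0.01, h2 = 0.1))
  r <- best_close_match("q", dm, toy_labels, threshold = 0.047)
  expect_equal(r$outcome, "ambiguous")

  # nearest heterospecific, nothing conspecific tied -> incorrect
  dm <- toy_ident_dm(c(c1 = 0.05, c2 = 0.05, h1 = 0.01, h2 = 0.1))
  r <- best_close_match("q", dm, toy_labels, threshold = 0.047)
  expect_equal(r$outcome, "incorrect")
})

test_that("near neighbour scores true iff a tied-nearest candidate is conspecific", {
  dm <- toy_ident_dm(c(c1 = 0.01, c2 = 0.03, h1 = 0.1, h2 = 0.1))
  expect_equal(near_neighbour("q", dm, toy_labels)$outcome, "true")

  dm <- toy_ident_dm(c(c1 = 0.05, c2 = 0.05, h1 = 0.01, h2 = 0.1))
  expect_equal(near_neighbour("q", dm, toy_labels)$outcome, "false")

  # tie between conspecific and heterospecific -> true (documented tie rule),
  # confirmed against exhaustive enumeration of the nearest set
  dm <- toy_ident_dm(c(c1 = 0.01, c2 = 0.05, h1 = 0.01, h2 = 0.1))
  r <- near_neighbour("q", dm, toy_labels)
  expect_equal(r$outcome, "true")
  d <- dm$d["q", setdiff(dm$ids, "q")]
  nearest_set <- names(d)[d == min(d)]
  expect_setequal(strsplit(r$matched_ids, ",")[[1]], nearest_set)
})

test_that("threshold identification uses the full inclusive radius", {
  # only conspecifics within 1% -> correct
  dm <- toy_ident_dm(c(c1 = 0.005, c2 = 0.009, h1 = 0.1, h2 = 0.1))
  r <- thresh_id("q", dm, toy_labels)
  expect_equal(r$outcome, "correct")
  expect_setequal(strsplit(r$matched_ids, ",")[[1]], c("c1", "c2"))

  # mixed candidate set -> ambiguous
  dm <- toy_ident_dm(c(c1 = 0.005, c2 = 0.05, h1 = 0.008, h2 = 0.1))
  expect_equal(thresh_id("q", dm, toy_labels)$outcome, "ambiguous")

  # only heterospecifics within radius -> incorrect
  dm <- toy_ident_dm(c(c1 = 0.05, c2 = 0.05, h1 = 0.008, h2 = 0.1))
  expect_equal(thresh_id("q", dm, toy_labels)$outcome, "incorrect")

  # nothing within radius -> no_id
  dm <- toy_ident_dm(c(c1 = 0.05, c2 = 0.05, h1 = 0.1, h2 = 0.1))
  expect_equal(thresh_id("q", dm, toy_labels)$outcome, "no_id")

  # the boundary is inclusive: a candidate at exactly the threshold counts
  dm <- toy_ident_dm(c(c1 = 0.01, c2 = 0.05, h1 = 0.1, h2 = 0.1))
  expect_equal(thresh_id("q", dm, toy_labels, threshold = 0.01)$outcome, "correct")
})

test_that("threshold extremes behave monotonically", {
  set.seed(103)
  for (rep in 1:10) {
    dm <- random_dm(6)
    labels <- setNames(sample(c("u", "v"), 6, replace = TRUE), dm$ids)
    if (length(unique(labels)) < 2) next
    for (id in dm$ids) {
      # infinite radius never abstains; vanishing radius always abstains
      expect_false(thresh_id(id, dm, labels, threshold = Inf)$outcome == "no_id")
      expect_equal(thresh_id(id, dm, labels, threshold = 1e-9)$outcome, "no_id")
      # raising the BCM threshold never turns an answer into no_id
      lo <- best_close_match(id, dm, labels, threshold = 0.05)$outcome
      hi <- best_close_match(id, dm, labels, threshold = 0.15)$outcome
      if (lo != "no_id") expect_equal(hi, lo)
    }
  }
})

test_that("best close match and near neighbour agree on unique close neighbours", {
  set.seed(107)
  for (rep in 1:10) {
    dm <- random_dm(7)
    labels <- setNames(sample(c("u", "v", "w"), 7, replace = TRUE), dm$ids)
    if (length(unique(labels)) < 2) next
    for (id in dm$ids) {
      d <- dm$d[id, setdiff(dm$ids, id)]
      if (sum(d == min(d)) == 1 && min(d) <= 0.15) {
        bcm <- best_close_match(id, dm, labels, threshold = 0.15)$outcome
        nn <- near_neighbour(id, dm, labels)$outcome
        expect_equal(bcm == "correct", nn == "true")
      }
    }
  }
})

test_that("evaluate_all tabulates counts and half-up percentages per criterion", {
  sim <- simulate_dataset(simulation_config(n_species = 3, n_per_species = c(4, 4, 4),
                                            intra_depth = 0.001, inter_depth = 0.08,
                                            seed = 29))
  dm <- k2p_matrix(sim$dataset)
  rep <- evaluate_all(sim$dataset, dm, bcm_threshold = 0.04)
  # perfectly separated data: everything correct / true
  for (cr in c("best_close_match", "thresh_id")) {
    sub <- rep$summary[rep$summary$criterion == cr, ]
    expect_equal(sub$n[sub$outcome == "correct"], 12)
    expect_equal(sub$pct[sub$outcome == "correct"], 100)
  }
  nn <- rep$summary[rep$summary$criterion == "near_neighbour", ]
  expect_equal(nn$n[nn$outcome == "true"], 12)
  # counts sum to n and percentages to 100 per criterion
  for (cr in unique(rep$summary$criterion)) {
    sub <- rep$summary[rep$summary$criterion == cr, ]
    expect_equal(sum(sub$n), 12)
    expect_lt(abs(sum(sub$pct) - 100), 0.02)
  }
})

test_that("percentages reproduce the two-decimal printed convention", {
  expect_equal(round_half_up(100 * 3 / 56, 2), 5.36)
  expect_equal(round_half_up(100 * 27 / 56, 2), 48.21)
  expect_equal(round_half_up(100 * 49 / 56, 2), 87.5)
  expect_equal(round_half_up(100 * 1 / 56, 2), 1.79)
  expect_equal(round_half_up(0.125 * 100, 2), 12.5)
})

test_that("query-side labels can differ from the reference labels", {
  dm <- toy_ident_dm(c(c1 = 0.01, c2 = 0.03, h1 = 0.1, h2 = 0.1))
  obs <- toy_labels
  obs["q"] <- "sp_y"  # field misidentification of the query
  r <- best_close_match("q", dm, labels = toy_labels, threshold = 0.047,
                        query_labels = obs)
  expect_equal(r$outcome, "incorrect")
})
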