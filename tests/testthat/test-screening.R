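# a small trained model + synthetic screening table shared across tests
scr_lib <- generate_library(synthetic_spec(n_compounds = 1500, n_features = 25,
                                           n_informative = 6, seed = 31L))
scr_model <- train_ros_model(scr_lib$descriptors, scr_lib$log_ros, rf_config(),
                             threshold = scr_lib$threshold)
scr_table <- generate_screen_table(scr_lib, 2000, seed = 32L)$descriptors

test_that("first-pass candidates are invariant to chunk size and row order", {
  base <- screen_first_pass(scr_table, scr_model, chunk_size = 5000)
  for (cs in c(1, 7, 123, nrow(scr_table))) {
    alt <- screen_first_pass(scr_table, scr_model, chunk_size = cs)
    expect_identical(alt$stage1$compound_id, base$stage1$compound_id)
    expect_equal(alt$stage1$prediction, base$stage1$prediction)
  }
  perm <- sample(nrow(scr_table))
  shuf <- screen_first_pass(scr_table[perm, ], scr_model, chunk_size = 500)
  expect_setequal(shuf$stage1$compound_id, base$stage1$compound_id)
  expect_equal(base$n_input, nrow(scr_table))
  expect_true(all(base$stage1$prediction >= scr_model$threshold))
})

test_that("file-based streaming matches in-memory screening", {
  p <- tempfile(fileext = ".csv")
  sub <- scr_table[1:500, ]
  write.table(data.frame(compound_id = rownames(sub), sub,
                         check.names = FALSE),
              p, sep = ",", row.names = FALSE, quote = FALSE)
  from_file <- screen_first_pass(p, scr_model, chunk_size = 123)
  in_mem <- screen_first_pass(sub, scr_model, chunk_size = 123)
  expect_identical(from_file$stage1$compound_id, in_mem$stage1$compound_id)
  expect_equal(from_file$stage1$prediction, in_mem$stage1$prediction,
               tolerance = 1e-10)
  expect_equal(from_file$n_input, 500)
})

test_that("malformed screening rows abort with a located error", {
  p <- tempfile(fileext = ".csv")
  writeLines(c("compound_id,f1,f2", "a,1,2", "b,not_a_number,3"), p)
  X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("f1", "f2")))
  m <- train_ros_model(X, rnorm(20), rf_config())
  expect_error(screen_first_pass(p, m, chunk_size = 10), "malformed|scan")
})

test_that("raising the threshold never grows the candidate set", {
  f1 <- screen_first_pass(scr_table, scr_model, threshold = 4.0)
  f2 <- screen_first_pass(scr_table, scr_model, threshold = 4.67)
  f3 <- screen_first_pass(scr_table, scr_model, threshold = 5.2)
  expect_true(all(f2$stage1$compound_id %in% f1$stage1$compound_id))
  expect_true(all(f3$stage1$compound_id %in% f2$stage1$compound_id))
  expect_true(f1$n_first_pass >= f2$n_first_pass)
  expect_true(f2$n_first_pass >= f3$n_first_pass)
})

test_that("a constant low-scoring model yields zero candidates", {
  X <- matrix(rnorm(100 * 2), 100, 2, dimnames = list(NULL, c("f1", "f2")))
  m <- train_ros_model(X, rep(c(2.9, 3.1), 50), rf_config())
  tab <- matrix(rnorm(50 * 2), 50, 2,
                dimnames = list(sprintf("s%02d", 1:50), c("f1", "f2")))
  f <- screen_first_pass(tab, m, threshold = 4.67)
  expect_equal(f$n_first_pass, 0)
})

test_that("compartment ids follow the row-major bottom-left convention", {
  g <- compartment_grid()
  expect_equal(assign_compartment(rbind(c(-1, -1)), g), 0L)
  expect_equal(assign_compartment(rbind(c(1, 1)), g), 63L)
  expect_equal(assign_compartment(rbind(c(0, 0)), g), 36L)
  expect_equal(assign_compartment(rbind(c(1, -1)), g), 7L)
  expect_equal(assign_compartment(rbind(c(-1, 1)), g), 56L)
  expect_error(assign_compartment(rbind(c(1.2, 0)), g), "outside")
})

test_that("compartment assignment matches a brute-force interval search", {
  set.seed(41)
  pts <- cbind(runif(10000, -1, 1), runif(10000, -1, 1))
  ids <- assign_compartment(pts)
  expect_identical(ids, naive_compartment(pts))
  expect_setequal(unique(ids), 0:63)
})

test_that("secondary selection matches an exhaustive rank enumeration", {
  for (s in 1:3) {
    set.seed(s)
    cand <- data.frame(compound_id = sprintf("c%02d", 1:50),
                       prediction = round(runif(50, 4.67, 6), 2),
                       stringsAsFactors = FALSE)
    cand_xy <- cbind(runif(50, -1, 1), runif(50, -1, 1))
    ref_xy <- cbind(runif(5, -1, 1), runif(5, -1, 1))
    funnel <- structure(list(n_input = 50, n_first_pass = 50,
                             stage1 = cand, stage2 = NULL,
                             n_second_pass = NULL,
                             threshold = 4.67, chunk_size = 50),
                        class = "screening_funnel")
    got <- secondary_select(funnel, cand_xy, ref_xy, quota = 3)
    expect_identical(sort(got$stage2$compound_id),
                     naive_secondary(cand, cand_xy, ref_xy, quota = 3))
  }
})

test_that("a co-located top-prediction candidate is selected first in its compartment", {
  cand <- data.frame(compound_id = c("star", "other1", "other2"),
                     prediction = c(6.0, 5.0, 4.9),
                     stringsAsFactors = FALSE)
  coords <- rbind(c(0.10, 0.10), c(0.2, 0.2), c(0.15, 0.12))
  refs <- rbind(c(0.10, 0.10))
  funnel <- structure(list(n_input = 3, n_first_pass = 3, stage1 = cand,
                           stage2 = NULL, n_second_pass = NULL,
                           threshold = 4.67, chunk_size = 10),
                      class = "screening_funnel")
  got <- secondary_select(funnel, coords, refs, quota = 1)
  expect_identical(got$stage2$compound_id, "star")
  expect_equal(got$stage2$rank_d, 1)
  expect_equal(got$stage2$rank_p, 1)
})

test_that("selection respects quotas, exclusions, and nestedness", {
  set.seed(42)
  n <- 120
  cand <- data.frame(compound_id = sprintf("c%03d", 1:n),
                     prediction = runif(n, 4.67, 6),
                     stringsAsFactors = FALSE)
  xy <- cbind(runif(n, -1, 1), runif(n, -1, 1))
  refs <- cbind(runif(10, -1, 1), runif(10, -1, 1))
  funnel <- structure(list(n_input = 5000, n_first_pass = n, stage1 = cand,
                           stage2 = NULL, n_second_pass = NULL,
                           threshold = 4.67, chunk_size = 100),
                      class = "screening_funnel")
  q2 <- secondary_select(funnel, xy, refs, quota = 2)
  q5 <- secondary_select(funnel, xy, refs, quota = 5)
  expect_true(all(q2$stage2$compound_id %in% q5$stage2$compound_id))
  expect_true(all(q5$stage2$compound_id %in% cand$compound_id))
  expect_lte(q5$n_second_pass, funnel$n_first_pass)

  q0 <- secondary_select(funnel, xy, refs, quota = 0)
  expect_equal(q0$n_second_pass, 0)

  banned <- q5$stage2$compound_id[1]
  q5b <- secondary_select(funnel, xy, refs, quota = 5, exclude = banned)
  expect_false(banned %in% q5b$stage2$compound_id)

  capped <- secondary_select(funnel, xy, refs, quota = 5, max_total = 7)
  expect_equal(capped$n_second_pass, 7)
  expect_error(secondary_select(funnel, xy, refs[0, , drop = FALSE]),
               "empty reference")
})

test_that("funnel reports recount the stored stages and mark missing stages", {
  f <- screen_first_pass(scr_table, scr_model)
  rep1 <- funnel_report(f)
  expect_equal(rep1$first_pass_candidates, nrow(f$stage1))
  expect_null(rep1$second_pass_candidates)
  expect_output(print(rep1), "stage not run")

  p <- tempfile(fileext = ".json")
  funnel_report(f, json_path = p)
  j <- jsonlite::read_json(p)
  expect_equal(j$total_screened, f$n_input)
  expect_equal(j$first_pass_candidates, f$n_first_pass)
})
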