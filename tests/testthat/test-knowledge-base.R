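test_that("augmentation yields exactly |bases| x |grid| candidates", {
  bases <- gen_base_collection(2, c(60, 80), seed = 4, f = 5)
  grid <- augmentation_grid()
  cands <- augment_instances(bases, grid, seed = 1, with_little = FALSE)
  expect_length(cands, 12)
  expect_length(augment_instances(bases[1], grid, seed = 1, with_little = FALSE), 6)
  expect_length(augment_instances(list(), grid, seed = 1), 0)
  expect_error(augment_instances(bases, list(), seed = 1), "non-empty")
  # Feasible candidates carry a fingerprint with f11 present.
  ok <- cands[vapply(cands, `[[`, TRUE, "feasible")]
  expect_gt(length(ok), 0)
  expect_true(all(vapply(ok, function(c) "f11" %in% names(c$fingerprint), TRUE)))
})

test_that("exclusion rules drop uncovered and degenerate candidates with reasons", {
  bases <- gen_base_collection(2, c(60, 60), seed = 9, f = 5)
  grid <- list(degradation_condition("c1", 0.2, 0.5, "MCAR"),
               degradation_condition("c2", 0.3, 0.5, "MCAR"))
  cands <- augment_instances(bases, grid, seed = 2, with_little = FALSE)

  perf_good <- c(m1 = 0.7, m2 = 0.6)
  lookup <- list()
  lookup[[paste(bases[[1]]$base_group, "c1", sep = "||")]] <- list(perf = perf_good)
  lookup[[paste(bases[[1]]$base_group, "c2", sep = "||")]] <- list(perf = c(m1 = 0.5, m2 = 0.45))
  lookup[[paste(bases[[2]]$base_group, "c1", sep = "||")]] <- list(perf = perf_good)
  # base 2 / c2 has no sweep entry at all.

  kb <- build_kb(cands, lookup, exclusion_rules(degeneracy_floor = 0.55))
  expect_length(kb, 2)
  excl <- attr(kb, "exclusions")
  expect_setequal(excl$reason, c("degenerate", "insufficient sweep coverage"))

  # Survivors carry the oracle as the argmax of their performance vector.
  for (i in kb$instances) {
    expect_identical(i$oracle_method, names(which.max(i$perf_vector)))
    expect_equal(i$oracle_auroc, max(i$perf_vector))
  }

  # Deterministic: the same inputs rebuild the same store.
  kb2 <- build_kb(cands, lookup, exclusion_rules(degeneracy_floor = 0.55))
  expect_equal(kb, kb2, ignore_attr = TRUE)

  # All candidates excluded -> empty-store error.
  expect_error(build_kb(cands, list(), exclusion_rules()), "empty store")
})

test_that("a fully covered, non-degenerate set survives exclusion intact", {
  bases <- gen_base_collection(3, c(60, 60), seed = 5, f = 5)
  grid <- list(degradation_condition("only", 0.2, 0.5, "MCAR"))
  cands <- augment_instances(bases, grid, seed = 3, with_little = FALSE)
  lookup <- setNames(
    rep(list(list(perf = c(m1 = 0.8, m2 = 0.7))), 3),
    paste(vapply(bases, function(b) b$base_group, ""), "only", sep = "||"))
  kb <- build_kb(cands, lookup)
  expect_length(kb, length(cands))
  expect_identical(nrow(attr(kb, "exclusions")), 0L)
})

test_that("stores round-trip through their text format field-for-field", {
  kb <- planted_fixture(n = 12L, m = 10L, noise = 0.03, seed = 21L, n_splits = 4L)
  path <- withr::local_tempfile(fileext = ".json")
  kb_write(kb, path)
  back <- kb_read(path)
  expect_identical(length(back), length(kb))
  expect_identical(back$method_ids, kb$method_ids)
  for (i in seq_along(kb$instances)) {
    a <- kb$instances[[i]]; b <- back$instances[[i]]
    expect_identical(b$instance_id, a$instance_id)
    expect_identical(b$base_group, a$base_group)
    expect_equal(b$fingerprint, a$fingerprint)
    expect_equal(b$perf_vector, a$perf_vector)
    expect_equal(b$perf_splits, a$perf_splits)
    expect_identical(b$oracle_method, a$oracle_method)
  }
})

test_that("partial performance vectors keep their missing-entry flags", {
  i1 <- mk_instance("p1", "g1", runif(10), c(m1 = 0.7, m2 = NA, m3 = 0.6))
  i2 <- mk_instance("p2", "g2", runif(10), c(m1 = 0.6, m2 = 0.8, m3 = 0.5))
  kb <- mk_kb(list(i1, i2))
  path <- withr::local_tempfile(fileext = ".json")
  kb_write(kb, path)
  back <- kb_read(path)
  expect_true(is.na(back$instances[[1]]$perf_vector["m2"]))
  expect_equal(back$instances[[1]]$perf_vector, i1$perf_vector)
})

test_that("malformed stores are rejected with the offending record named", {
  kb <- planted_fixture(n = 5L, m = 10L, seed = 2L)
  path <- withr::local_tempfile(fileext = ".json")
  kb_write(kb, path)
  doc <- jsonlite::read_json(path)
  doc$instances[[3]]$perf_vector[[1]] <- 1.5
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  expect_error(kb_read(path), "pk-003")

  doc$version <- "other/9"
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  expect_error(kb_read(path), "version")
})
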