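test_that("the movement registry has 19 codes with the six gestalt members", {
  reg <- movement_codes()
  expect_equal(nrow(reg), 19)
  expect_equal(reg$code_id, 1:19)
  expect_equal(reg$code_id[reg$in_pain_gestalt], c(3L, 5L, 6L, 7L, 17L, 18L))
  expect_equal(reg$label[c(3, 5, 6, 7, 17, 18)],
               c("Brow Lowerer", "Nose Wrinkle", "Upper-Lip Raiser",
                 "Nasolabial Furrow", "Lips Parting", "Mouth Stretch"))
})

test_that("read_annotations parses, validates and reports schema errors by row", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(make_annotations(c(0.2, 1.1), c(3, 5)), path)
  ann <- read_annotations(path)
  expect_equal(nrow(ann), 2)
  expect_equal(nrow(unique(ann[c("fetus_id", "session_id")])), 1)

  readr::write_csv(make_annotations(c(0.2, 1.1), c(3, 20)), path)
  expect_error(read_annotations(path), "20.*row.*2|row.*2.*20")

  readr::write_csv(make_annotations(-0.5, 3), path)
  expect_error(read_annotations(path), "onset")

  readr::write_csv(make_annotations(numeric(0), integer(0)), path)
  expect_warning(empty <- read_annotations(path), "no rows")
  expect_equal(nrow(empty), 0)
})

test_that("an unbalanced study (59 of 60 sessions) reads through intact", {
  design <- simulation_design(seed = 21)
  ann <- simulate_annotations(design)$annotations
  ann <- dplyr::filter(ann, !(fetus_id == "f01" & gestational_age_weeks == 24))
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(ann, path)
  got <- read_annotations(path)
  expect_equal(nrow(unique(got[c("fetus_id", "session_id")])), 59)
})

test_that("chain clustering follows the worked examples", {
  ann <- make_annotations(c(0, 0.5, 3), c(3, 5, 3))
  ev <- summarise_events(cluster_events(ann))
  expect_equal(ev$n_members, c(2, 1))
  expect_equal(ev$complexity_all, c(2, 1))

  # closure across consecutive <= 1 s gaps even though 0 -> 1.8 exceeds 1 s
  chain <- make_annotations(c(0, 0.9, 1.8), c(1, 2, 4))
  ev2 <- summarise_events(cluster_events(chain))
  expect_equal(nrow(ev2), 1)
  expect_equal(ev2$n_members, 3)

  # anchor rule splits that same stream at the window boundary
  ev3 <- summarise_events(cluster_events(chain, rule = "anchor"))
  expect_equal(ev3$n_members, c(2, 1))

  expect_equal(nrow(cluster_events(make_annotations(numeric(0), integer(0)))), 0)
})

test_that("a gap of exactly one second co-occurs (boundary tolerance)", {
  ann <- make_annotations(c(0, 1.0, 2.0 + 1e-12), c(3, 5, 6))
  ev <- summarise_events(cluster_events(ann))
  expect_equal(nrow(ev), 1)
  ann2 <- make_annotations(c(0, 1.0 + 1e-6), c(3, 5))
  expect_equal(nrow(summarise_events(cluster_events(ann2))), 2)
})

test_that("clustering partitions annotations and agrees with the brute-force oracle", {
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(1:50, 1)
    onsets <- sort(runif(n, 0, sample(c(5, 20, 60), 1)))
    ann <- make_annotations(onsets, sample(1:19, n, replace = TRUE))
    cl <- cluster_events(ann)
    # partition: every annotation in exactly one event
    expect_equal(nrow(cl), n)
    expect_false(any(is.na(cl$event)))
    # oracle equivalence: same partition as transitive closure
    expect_equal(as.integer(factor(cl$event)), brute_force_events(onsets))
    # every member within 1 s of some other member (singletons exempt)
    for (e in split(cl$onset_s, cl$event)) {
      if (length(e) > 1) {
        mind <- vapply(seq_along(e), function(i)
          min(abs(e[-i] - e[i])), numeric(1))
        expect_lte(max(mind), 1 + 1e-9)
      }
    }
  }
})

test_that("widening the window never increases the number of events", {
  set.seed(7)
  for (rep in 1:10) {
    onsets <- sort(runif(30, 0, 40))
    ann <- make_annotations(onsets, sample(1:19, 30, replace = TRUE))
    n_events <- vapply(c(0.25, 0.5, 1, 2, 4), function(w)
      max(cluster_events(ann, window_s = w)$event), numeric(1))
    expect_true(all(diff(n_events) <= 0))
  }
})

test_that("event_complexity counts distinct codes in the chosen subset", {
  expect_equal(event_complexity(c(3, 5, 17), "gestalt"), 3)
  expect_equal(event_complexity(c(1, 2, 4), "gestalt"), 0)
  expect_equal(event_complexity(c(3, 3, 5), "all"), 2)
  expect_error(event_complexity(integer(0)), "at least one member")
})

test_that("complexity counts distinct codes and the gestalt subset dominates", {
  ann <- make_annotations(c(0, 0.3, 0.6), c(3, 3, 5))
  ev <- summarise_events(cluster_events(ann))
  expect_equal(ev$complexity_all, 2)    # repeated code counts once
  expect_equal(ev$complexity_gestalt, 2)

  ann2 <- make_annotations(c(0, 0.2, 0.4), c(1, 2, 4))
  ev2 <- summarise_events(cluster_events(ann2))
  expect_equal(ev2$complexity_gestalt, 0)

  set.seed(11)
  big <- make_annotations(sort(runif(80, 0, 120)),
                          sample(1:19, 80, replace = TRUE))
  evb <- summarise_events(cluster_events(big))
  expect_true(all(evb$complexity_gestalt <= evb$complexity_all))
  expect_true(all(evb$complexity_all <= 19))
  expect_true(all(evb$complexity_gestalt <= 6))
})

test_that("ordinal categorisation caps at the top category per scheme", {
  expect_equal(to_ordinal_category(7, "all"), 6L)
  expect_equal(to_ordinal_category(1, "gestalt"), 1L)
  expect_equal(to_ordinal_category(6, "gestalt"), 5L)
  expect_equal(to_ordinal_category(1:7, "all"), c(1:5, 6L, 6L))
  expect_error(to_ordinal_category(0, "all"), "excluded")
})

test_that("tabulate_counts groups by age bin and by session consistently", {
  design <- simulation_design(seed = 5)
  bundle <- simulate_annotations(design)
  tab_age <- tabulate_counts(bundle$annotations, scheme = "gestalt", by = "age_bin")
  tab_sess <- tabulate_counts(bundle$annotations, scheme = "gestalt", by = "session")
  expect_equal(tab_age$age_weeks, c(24, 28, 32, 36))
  expect_equal(sum(tab_age$total), sum(tab_sess$total))
  # session-level rows re-aggregate to the age-bin table
  re <- dplyr::summarise(
    dplyr::group_by(tab_sess, age_weeks = round(gestational_age_weeks)),
    dplyr::across(dplyr::starts_with("cat_"), sum), total = sum(total))
  expect_equal(as.data.frame(re), as.data.frame(tab_age))

  # gestalt totals cannot exceed all-movement totals
  tab_all <- tabulate_counts(bundle$annotations, scheme = "all", by = "age_bin")
  expect_true(all(tab_age$total <= tab_all$total))

  expect_equal(nrow(tabulate_counts(make_annotations(numeric(0), integer(0)))), 0)

  odd <- make_annotations(0.5, 3, age = 21)
  expect_error(tabulate_counts(odd, by = "age_bin"), "nominal")
})

test_that("row percentages reproduce the published tables exactly at 1 d.p.", {
  for (scheme in c("all", "gestalt")) {
    got <- row_percentages(reference_counts(scheme))
    expect_equal(as.data.frame(got), as.data.frame(reference_percentages(scheme)),
                 tolerance = 0)
  }
  one <- tibble::tibble(cat_1 = 10L, cat_2 = 0L, cat_3 = 0L, cat_4 = 0L,
                        cat_5 = 0L, total = 10L)
  expect_equal(unlist(row_percentages(one)[1, 1:5], use.names = FALSE),
               c(100, 0, 0, 0, 0))
  bad <- dplyr::mutate(one, total = 0L)
  expect_error(row_percentages(bad), "zero total")
})

test_that("percentage rounding is half-up, not banker's", {
  # 0.25% must print as 0.3, where round() would give 0.2
  tab <- tibble::tibble(cat_1 = 1L, cat_2 = 399L, total = 400L)
  expect_equal(row_percentages(tab)$cat_1, 0.3)
})

test_that("rebase_onsets maps raw scan time to accumulated codable time", {
  segs <- tibble::tibble(fetus_id = "f1", session_id = "s1",
                         start_s = c(10, 100), end_s = c(40, 130))
  ann <- make_annotations(c(12, 39.5, 100.2), c(3, 5, 6))
  out <- rebase_onsets(ann, segs)
  expect_equal(out$onset_s, c(2, 29.5, 30.2))
  # the pause between 39.5 and 100.2 vanishes: they now co-occur
  expect_equal(max(cluster_events(out)$event), 2)
  outside <- make_annotations(50, 3)
  expect_error(rebase_onsets(outside, segs), "outside")
})
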