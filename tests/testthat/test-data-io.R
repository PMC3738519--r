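test_that("condition constructors enforce their invariants", {
  expect_error(condition_rts("av", c(250, -3), soa = 0), "finite latencies")
  expect_error(condition_rts("av", 250, soa = 35), "design grid")
  expect_error(condition_rts("av", c(250, NA), soa = 0), "NA")
  x <- condition_rts("av", c(250, Inf, 310), soa = -40)
  expect_equal(n_finite(x), 2L)
  expect_error(toj_table(c(0, 0), c(1, 1), c(10, 10)), "strictly increasing")
  expect_error(toj_table(c(-20, 20), c(5, 61), c(10, 60)), "rows: 2")
  expect_error(
    participant_data("p", list(catch = condition_rts("catch")),
                     toj_table(0, 3, 10)),
    "missing RT conditions")
})

test_that("the 26 condition keys map bijectively onto the dataset legend order", {
  keys <- all_condition_keys()
  expect_length(keys, 26L)
  expect_identical(anyDuplicated(keys), 0L)
  expect_identical(keys[1], "catch")
  expect_identical(keys[2], "auditory_only")
  expect_identical(keys[26], "visual_only")
  # indices 3..25 are the SOAs in ascending order, -400 first
  soas <- as.integer(sub("^av_", "", keys[3:25]))
  expect_identical(soas, soa_grid())
  expect_identical(soas[1], -400L)
  expect_identical(soas[23], 400L)
  # every key round-trips through condition_key()
  for (i in seq_along(soas))
    expect_identical(condition_key("av", soas[i]), keys[2 + i])
})

test_that("native CSV round trip is lossless for a synthetic study", {
  cfg <- synth_config(n_participants = 2, n_trials = 12, seed = 31)
  st <- make_study(cfg)
  dir <- withr::local_tempdir()
  paths <- write_native(st, dir)
  st2 <- read_native(paths[["rt"]], paths[["toj"]], paths[["metadata"]])
  expect_length(st2$participants, 2L)
  for (i in 1:2) {
    p1 <- st$participants[[i]]; p2 <- st2$participants[[i]]
    expect_identical(p1$id, p2$id)
    for (key in all_condition_keys()) {
      expect_equal(sort(p2$rt[[key]]$latencies), sort(p1$rt[[key]]$latencies),
                   tolerance = 1e-12)
      expect_identical(p2$rt[[key]]$soa, p1$rt[[key]]$soa)
    }
    expect_equal(as.data.frame(p2$toj), as.data.frame(p1$toj))
  }
  # ground-truth metadata survives the round trip
  expect_equal(st2$metadata$seed, st$metadata$seed)
  expect_equal(st2$metadata$ground_truth$toj_params[[1]]$sigma,
               st$metadata$ground_truth$toj_params[[1]]$sigma)
})

test_that("read_native handles a minimal file and rejects invalid rows", {
  dir <- withr::local_tempdir()
  rt <- file.path(dir, "rt.csv"); toj <- file.path(dir, "toj.csv")
  writeLines(c("participant,condition,soa,latency", "1,av,0,250"), rt)
  writeLines(c("participant,soa,visual_first,n", "1,0,3,10"), toj)
  st <- read_native(rt, toj)
  expect_length(st$participants, 1L)
  av0 <- get_condition(st$participants[[1]], "av", 0)
  expect_equal(av0$latencies, 250)
  # other conditions exist but are empty
  expect_length(get_condition(st$participants[[1]], "catch")$latencies, 0L)

  writeLines(c("participant,soa,visual_first,n", "1,0,61,60"), toj)
  expect_error(read_native(rt, toj), "invalid counts")
  writeLines(c("participant,soa,visual_first,n", "1,0,3,10"), toj)
  writeLines(c("participant,condition,soa,latency", "1,av,0,-5"), rt)
  expect_error(read_native(rt, toj), "latencies")
  writeLines(c("participant,condition,soa,latency", "1,av,35,250"), rt)
  expect_error(read_native(rt, toj), "off the design grid")
  # the inf token parses to an infinite latency
  writeLines(c("participant,condition,soa,latency",
               "1,av,0,250", "1,av,0,inf"), rt)
  st <- read_native(rt, toj)
  expect_equal(sort(get_condition(st$participants[[1]], "av", 0)$latencies),
               c(250, Inf))
})

test_that("the MAT-container layout reads with legend mapping and flags", {
  mat <- file.path(withr::local_tempdir(), "study.mat")
  # build a tiny container with the documented shape: struct of
  # participants, each a 26-row RT cell array and a 23x3 TOJ array
  py <- sprintf('
import numpy as np
from scipy.io import savemat
soas = [-400,-300,-250,-200,-150,-120,-100,-80,-60,-40,-20,0,20,40,60,80,100,120,150,200,250,300,400]
def participant(base):
    rt = np.empty((26, 3), dtype=object)
    for i in range(26):
        if i == 0:
            rt[i] = [np.array([[np.inf]]), np.array([[base + 900.0]]), np.array([[np.inf]])]
        else:
            rt[i] = [np.array([[base + 10.0 * i]]), np.array([[base + 10.0 * i + 5]]), np.array([[np.inf]])]
    toj = np.column_stack([soas, np.arange(23), np.full(23, 60)]).astype(float)
    return {"RT": rt, "TOJ": toj}
savemat("%s", {"data": {"p1": participant(200.0), "p2": participant(300.0)}})
', mat)
  res <- system2("python", "-", input = py, stdout = TRUE, stderr = TRUE)
  expect_null(attr(res, "status"))

  st <- read_dataset_s1(mat)
  expect_length(st$participants, 2L)
  expect_true(st$metadata$kill_the_twin_already_applied)
  expect_true(st$metadata$toj_false_alarms_already_excluded)
  p1 <- st$participants[[1]]
  # legend order: row 1 catch, row 2 auditory-only, row 3 SOA -400, row 26 visual-only
  expect_equal(sort(get_condition(p1, "catch")$latencies), c(1100, Inf, Inf))
  expect_equal(sort(get_condition(p1, "auditory_only")$latencies), c(210, 215, Inf))
  expect_equal(sort(get_condition(p1, "av", -400)$latencies), c(220, 225, Inf))
  expect_equal(sort(get_condition(p1, "av", 0)$latencies), c(330, 335, Inf))
  expect_equal(sort(get_condition(p1, "visual_only")$latencies), c(450, 455, Inf))
  expect_equal(p1$toj$soa, soa_grid())
  expect_equal(p1$toj$visual_first, 0:22)

  # wrong RT shape reported with the expected row count
  py_bad <- sprintf('
import numpy as np
from scipy.io import savemat
rt = np.empty((25, 1), dtype=object)
for i in range(25): rt[i] = [np.array([[250.0]])]
toj = np.zeros((23, 3))
savemat("%s", {"data": {"p1": {"RT": rt, "TOJ": toj}}})
', mat)
  system2("python", "-", input = py_bad, stdout = TRUE, stderr = TRUE)
  expect_error(read_dataset_s1(mat), "26")
})
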