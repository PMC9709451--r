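test_that("component markers interpolate linearly between anchors", {
  scaffold <- data.frame(marker = c("A", "B"), chr = 1L,
                         pos_cm = c(100, 120))
  comp <- data.frame(map_id = "m1", marker = c("A", "M", "B"), chr = 1L,
                     pos_cm = c(10, 15, 20))
  res <- build_consensus(scaffold, list(m1 = comp))
  expect_equal(res$map$pos_cm[res$map$marker == "M"], 110)
  expect_equal(res$report$n_added, 1L)
  # scaffold positions never altered
  expect_equal(res$map$pos_cm[res$map$marker == "A"], 100)
  expect_equal(res$map$pos_cm[res$map$marker == "B"], 120)
})

test_that("a marker tied with an anchor is placed at the anchor then tie-broken", {
  scaffold <- data.frame(marker = c("A", "B"), chr = 1L, pos_cm = c(100, 120))
  comp <- data.frame(map_id = "m1", marker = c("A", "M", "B"), chr = 1L,
                     pos_cm = c(10, 10, 20))
  res <- build_consensus(scaffold, list(m1 = comp))
  pm <- res$map$pos_cm[res$map$marker == "M"]
  expect_gt(pm, 100)          # bumped strictly after the scaffold anchor
  expect_lt(pm - 100, 1e-9)
  expect_true(all(diff(res$map$pos_cm[order(res$map$pos_cm)]) > 0))
})

test_that("anchor order conflicts drop the component's new markers with reason", {
  scaffold <- data.frame(marker = c("A", "B"), chr = 1L, pos_cm = c(100, 120))
  # component sees B before A: order inverted relative to the scaffold
  comp <- data.frame(map_id = "m1", marker = c("B", "M1", "M2", "A"),
                     chr = 1L, pos_cm = c(0, 5, 8, 10))
  res <- build_consensus(scaffold, list(m1 = comp))
  expect_equal(res$report$n_dropped, 2L)
  expect_equal(unique(res$dropped$reason), "anchor order conflict")
  expect_equal(sort(res$dropped$marker), c("M1", "M2"))
  expect_equal(nrow(res$map), 2)  # scaffold unchanged
})

test_that("terminal markers extrapolate with the mean ratio and cap at chromosome ends", {
  scaffold <- data.frame(marker = c("A", "B", "Z"), chr = 1L,
                         pos_cm = c(10, 30, 40))
  # anchors A, B; component spans src 0..20 so ratio = (30-10)/(20-0) = 1
  comp <- data.frame(map_id = "m1",
                     marker = c("M0", "A", "B", "M9"),
                     chr = 1L, pos_cm = c(5, 10, 30, 50))
  # ratio = 20/20 = 1; M0 -> 10 - 5 = 5 < chr start 10 -> dropped;
  # M9 -> 30 + 20 = 50 > chr end 40 -> dropped
  res <- build_consensus(scaffold, list(m1 = comp))
  expect_equal(res$report$n_dropped, 2L)
  expect_true(all(res$dropped$reason == "extrapolation out of range"))
})

test_that("fewer than two shared anchors skips the chromosome non-fatally", {
  scaffold <- data.frame(marker = c("A", "B"), chr = 1L, pos_cm = c(0, 50))
  comp <- data.frame(map_id = "m1", marker = c("A", "M"), chr = 1L,
                     pos_cm = c(0, 5))
  res <- build_consensus(scaffold, list(m1 = comp))
  expect_match(res$report$note, "fewer than 2 shared anchors")
  expect_equal(nrow(res$map), 2)
})

test_that("integration preserves within-interval marker order", {
  scaffold <- data.frame(marker = c("A", "B"), chr = 1L, pos_cm = c(0, 200))
  set.seed(3)
  src <- sort(runif(20, 1, 9))
  comp <- data.frame(map_id = "m1",
                     marker = c("A", sprintf("M%02d", 1:20), "B"),
                     chr = 1L, pos_cm = c(0, src, 10))
  res <- build_consensus(scaffold, list(m1 = comp))
  placed <- res$map[grepl("^M", res$map$marker), ]
  placed <- placed[match(sprintf("M%02d", 1:20), placed$marker), ]
  expect_true(all(diff(placed$pos_cm) > 0))
})

test_that("zero components returns the scaffold unchanged", {
  scaffold <- toy_scaffold()
  res <- build_consensus(scaffold, list())
  expect_equal(res$map$marker, scaffold$marker)
  expect_equal(res$map$pos_cm, scaffold$pos_cm)
  expect_equal(nrow(res$report), 0)
})

test_that("map statistics report lengths, densities, and degenerate chromosomes", {
  map <- data.frame(marker = c("a", "b", "c", "d", "e", "f"),
                    chr = c(1, 1, 1, 2, 2, 3),
                    pos_cm = c(0, 50, 100, 0, 200, 7))
  s <- map_statistics(map)
  p <- s$per_chromosome
  expect_equal(p$length_cm, c(100, 200, 7))
  expect_equal(p$density_cm[1], 50)
  expect_true(is.na(p$density_cm[3]))       # single marker: undefined
  expect_equal(s$cumulative_length_cm, 307)
})
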