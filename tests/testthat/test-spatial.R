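# Small deterministic test images are built inline; randomised labelings
# exercise the distance machinery against the all-pairs oracle.

toy_image <- function(values, pixel_size_um = 1) {
  colony_image(list(M = values), pixel_size_um,
               mask = matrix(TRUE, nrow(values), ncol(values)))
}

random_labels <- function(nr = 50, nc = 50, p_proto = 0.08) {
  lab <- matrix(2L, nr, nc)
  lab[matrix(runif(nr * nc) < p_proto, nr, nc)] <- 1L
  if (!any(lab == 1L)) lab[1, 1] <- 1L
  structure(list(labels = lab, marker = "M", cutoff = 0.3,
                 pixel_size_um = 1), class = "pixel_classification")
}

test_that("channel normalisation is min-max over the colony mask", {
  ch <- matrix(c(100, 350, 600, 200), 2, 2)
  img <- toy_image(ch)
  nm <- normalize_channel(img, "M")
  expect_equal(nm[2, 1], 0.5)       # value 350 between 100 and 600
  expect_equal(min(nm), 0)
  expect_equal(max(nm), 1)
  expect_false(attr(nm, "degenerate"))

  # constant channel: all zeros with a flag
  flat <- normalize_channel(toy_image(matrix(5, 3, 3)), "M")
  expect_true(all(flat == 0))
  expect_true(attr(flat, "degenerate"))

  expect_error(normalize_channel(img, "missing"), "no channel")

  # masked normalisation ignores background pixels
  mask <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2)
  img2 <- colony_image(list(M = ch), 1, mask = mask)
  nm2 <- normalize_channel(img2, "M")
  expect_equal(range(nm2[mask]), c(0, 1))
})

test_that("pixel classification thresholds normalised intensity", {
  # masked values normalise to 0, 0.35, 1
  ch <- matrix(c(0, 35, 100, 0), 2, 2)
  mask <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2)
  img <- colony_image(list(M = ch), 1, mask = mask)
  c03 <- classify_pixels(img, "M", 0.3)
  c04 <- classify_pixels(img, "M", 0.4)
  expect_equal(c03$labels[2, 1], 1L)  # 0.35 >= 0.3: prototroph
  expect_equal(c04$labels[2, 1], 2L)  # 0.35 <  0.4: auxotroph
  expect_equal(c03$labels[2, 2], 0L)  # outside mask: background

  # all-zero channel: every masked pixel auxotroph
  z <- classify_pixels(toy_image(matrix(0, 3, 3) + 1e-9 * diag(3)), "M", 0.5)
  expect_true(all(z$labels[c(2, 3, 4, 6, 7, 8)] == 2L))

  expect_error(classify_pixels(img, "M", 0), "strictly in")
  expect_error(classify_pixels(img, "M", 1), "strictly in")
})

test_that("unit and diagonal neighbour distances are exact", {
  ch <- matrix(0, 3, 3)
  ch[2, 2] <- 100
  img <- toy_image(ch, pixel_size_um = 0.65)
  cls <- classify_pixels(img, "M", 0.5)
  d <- nearest_prototroph_distances(cls)
  expect_equal(attr(d, "status"), "ok")
  expect_length(d, 8L)
  expect_equal(sort(unique(round(d / 0.65, 10))), c(1, sqrt(2)))
})

test_that("distance transform equals the all-pairs brute force exactly", {
  set.seed(19)
  for (i in 1:12) {
    cls <- random_labels(sample(20:100, 1), sample(20:100, 1),
                         p_proto = runif(1, 0.02, 0.3))
    d <- nearest_prototroph_distances(cls)
    ax <- which(cls$labels == 2L, arr.ind = TRUE)
    expect_identical(length(d), nrow(ax))
    expect_equal(sort(d), sort(oracle_nn_distances(cls$labels)),
                 tolerance = 1e-12)
  }
})

test_that("distances scale linearly with pixel size", {
  set.seed(29)
  cls <- random_labels(40, 40)
  d1 <- nearest_prototroph_distances(cls, pixel_size_um = 1)
  d2 <- nearest_prototroph_distances(cls, pixel_size_um = 2.5)
  expect_equal(d2, 2.5 * d1)
})

test_that("missing producers or auxotrophs yield explicit statuses", {
  all_proto <- structure(list(labels = matrix(1L, 4, 4), marker = "M",
                              cutoff = 0.2, pixel_size_um = 1),
                         class = "pixel_classification")
  d <- nearest_prototroph_distances(all_proto)
  expect_equal(attr(d, "status"), "no_auxotroph")
  s <- summarize_distances(d)
  expect_equal(s$status, "no_auxotroph")
  expect_true(is.na(s$mean_um))

  all_aux <- structure(list(labels = matrix(2L, 4, 4), marker = "M",
                            cutoff = 0.2, pixel_size_um = 1),
                       class = "pixel_classification")
  expect_equal(attr(nearest_prototroph_distances(all_aux), "status"),
               "no_producer")
})

test_that("distance summaries report order statistics in micrometres", {
  s <- summarize_distances(rep(3.2, 5))
  expect_equal(c(s$min_um, s$mean_um, s$max_um, s$p_um), rep(3.2, 4))

  s10 <- summarize_distances(1:10)
  expect_equal(s10$p_um, 9.1)  # linear interpolation between ranks
  expect_equal(s10$min_um, 1)
  expect_equal(s10$max_um, 10)

  s1 <- summarize_distances(4.2)
  expect_equal(c(s1$min_um, s1$mean_um, s1$max_um, s1$p_um), rep(4.2, 4))
  expect_true(s10$min_um <= s10$mean_um && s10$mean_um <= s10$max_um &&
                s10$p_um <= s10$max_um)
})

test_that("the proximity sweep covers markers x cutoffs with monotone structure", {
  fx <- community_fixture()
  spec <- image_spec(HLUM, fx, shape = c(120L, 120L), n_cells = 120L,
                     cell_radius_px = 3, noise_sd = 20, seed = 44)
  img <- gen_colony_image(spec)$image
  sw <- proximity_sweep(img)
  expect_equal(nrow(sw), 4 * 4)  # 4 markers x 4 cutoffs
  expect_setequal(unique(sw$marker), HLUM$id)

  for (mk in HLUM$id) {
    n_proto <- vapply(c(0.1, 0.2, 0.3, 0.4), function(cf)
      sum(classify_pixels(img, mk, cf)$labels == 1L), numeric(1))
    expect_true(all(diff(n_proto) <= 0))  # prototroph set shrinks
  }
})

test_that("raising the cutoff never brings a producer closer", {
  set.seed(55)
  for (i in 1:5) {
    ch <- matrix(runif(900), 30, 30)
    img <- toy_image(ch)
    prev <- NULL
    for (cf in c(0.2, 0.4, 0.6)) {
      cls <- classify_pixels(img, "M", cf)
      if (!any(cls$labels == 1L)) break
      dmap_aux <- nearest_prototroph_distances(cls)
      ax <- which(cls$labels == 2L, arr.ind = TRUE)
      cur <- array(NA_real_, dim(ch))
      cur[ax] <- dmap_aux
      if (!is.null(prev)) {
        both <- !is.na(prev) & !is.na(cur)
        expect_true(all(cur[both] >= prev[both] - 1e-12))
      }
      prev <- cur
    }
  }
})

test_that("cell-mode distances are one per connected auxotrophic component", {
  ch <- matrix(100, 6, 6)
  ch[1:2, 1:2] <- 0   # one auxotrophic blob
  ch[5:6, 5:6] <- 0   # another
  img <- toy_image(ch)
  cls <- classify_pixels(img, "M", 0.5)
  d <- nearest_prototroph_distances(cls, mode = "cell")
  expect_length(d, 2L)
  expect_true(all(d >= 1))
})
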