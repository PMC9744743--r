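test_that("charged-group centroids follow the residue chemistry", {
  lys <- data.frame(chain = "A", resno = 1L,
                    elety = c("CA", "CB", "NZ"),
                    x = c(0, 0.5, 1), y = c(0, 1, 2), z = c(0, 2, 3))
  expect_equal(charged_group_centroid(lys, "K")$coord,
               c(x = 1, y = 2, z = 3))
  arg <- data.frame(chain = "A", resno = 1L,
                    elety = c("NH1", "NH2", "NE"),
                    x = c(0, 2, 1), y = c(0, 0, 3), z = c(0, 0, 0))
  expect_equal(unname(charged_group_centroid(arg, "R")$coord), c(1, 1, 0))
  ## fallbacks when the charged group is missing
  stub <- data.frame(chain = "A", resno = 1L, elety = c("CA", "CB"),
                     x = c(0, 5), y = c(0, 5), z = c(0, 5))
  cg <- charged_group_centroid(stub, "K")
  expect_equal(unname(cg$coord), c(5, 5, 5))
  expect_equal(cg$flag, "cb_fallback")
  ca_only <- stub[stub$elety == "CA", ]
  expect_equal(charged_group_centroid(ca_only, "K")$flag, "ca_fallback")
  expect_error(charged_group_centroid(lys, "S"), "not basic")
})

test_that("small cluster configurations behave as specified", {
  ## equilateral 7 A triangle: one complete cluster of 3
  tri <- site_cloud(rbind(c(0, 0, 0), c(7, 0, 0),
                          c(3.5, 7 * sqrt(3) / 2, 0)))
  cl <- find_spatial_clusters(tri$model, tri$surface)
  expect_length(cl$clusters, 1)
  expect_equal(nrow(cl$clusters[[1]]$members), 3)
  expect_true(cl$clusters[[1]]$complete)
  expect_true(all(cl$clusters[[1]]$pairs$band == "short"))

  ## 12 A apart: in no band, no cluster
  none <- site_cloud(rbind(c(0, 0, 0), c(12, 0, 0)))
  expect_length(find_spatial_clusters(none$model, none$surface)$clusters,
                0)

  ## a 6 A pair: one incomplete cluster of 2
  pair <- site_cloud(rbind(c(0, 0, 0), c(6, 0, 0)))
  cl2 <- find_spatial_clusters(pair$model, pair$surface)
  expect_length(cl2$clusters, 1)
  expect_false(cl2$clusters[[1]]$complete)

  ## 20 A apart: long band only, and only when enabled
  far <- site_cloud(rbind(c(0, 0, 0), c(20, 0, 0)))
  expect_length(find_spatial_clusters(far$model, far$surface)$clusters, 1)
  expect_length(find_spatial_clusters(far$model, far$surface,
                                      use_long = FALSE)$clusters, 0)
})

test_that("buried or non-basic residues never participate", {
  pair <- site_cloud(rbind(c(0, 0, 0), c(6, 0, 0), c(3, 5, 0)))
  pair$surface$exposed[3] <- FALSE
  cl <- find_spatial_clusters(pair$model, pair$surface)
  expect_equal(sort(cl$clusters[[1]]$members$resno), c(1, 2))
})

test_that("sequence-adjacent member pairs are annotated as seeds", {
  cloud <- site_cloud(rbind(c(0, 0, 0), c(3.8, 0, 0), c(1.9, 7, 0)),
                      resno = c(1L, 2L, 10L))
  ## residues 1 and 2 are sequence-adjacent; edges go through residue 10
  cl <- find_spatial_clusters(cloud$model, cloud$surface)
  expect_length(cl$clusters, 1)
  adj <- cl$clusters[[1]]$adjacent_pairs
  expect_equal(nrow(adj), 1)
  expect_equal(c(adj$resno_i, adj$resno_j), c(1, 2))
})

test_that("components match the brute-force oracle on random site clouds", {
  set.seed(33)
  bands <- distance_bands()
  for (rep in 1:40) {
    n <- sample(5:50, 1)
    tips <- matrix(runif(n * 3, 0, 28), ncol = 3)
    cloud <- site_cloud(tips)
    cl <- find_spatial_clusters(cloud$model, cloud$surface, bands = bands)
    membership <- -seq_len(n)  # unique singleton labels
    for (k in seq_along(cl$clusters)) {
      membership[cl$clusters[[k]]$members$resno] <- k
    }
    got <- canon_groups(membership)
    want <- canon_groups(oracle_partition(tips, bands))
    expect_equal(got, want)
  }
})

test_that("clusters are invariant under rigid-body transforms", {
  set.seed(44)
  tips <- matrix(runif(30, 0, 25), ncol = 3)
  cloud <- site_cloud(tips)
  cl1 <- find_spatial_clusters(cloud$model, cloud$surface)
  th <- 1.1
  rot <- matrix(c(1, 0, 0, 0, cos(th), -sin(th), 0, sin(th), cos(th)), 3,
                byrow = TRUE)
  m2 <- cloud$model
  xyz <- as.matrix(m2$atoms[, c("x", "y", "z")]) %*% t(rot)
  m2$atoms[, c("x", "y", "z")] <- xyz + 7
  cl2 <- find_spatial_clusters(m2, cloud$surface)
  mem <- function(cl) lapply(cl$clusters, function(c) c$members$resno)
  expect_equal(mem(cl1), mem(cl2))
})

test_that("widening a band never removes an edge, and distances verify", {
  set.seed(55)
  tips <- matrix(runif(36, 0, 22), ncol = 3)
  cloud <- site_cloud(tips)
  narrow <- find_spatial_clusters(cloud$model, cloud$surface,
                                  bands = distance_bands(c(6, 9)),
                                  use_long = FALSE)
  wide <- find_spatial_clusters(cloud$model, cloud$surface,
                                bands = distance_bands(c(5, 10)),
                                use_long = FALSE)
  edges <- function(cl) {
    do.call(rbind, lapply(cl$clusters, function(c)
      c$pairs[, c("resno_i", "resno_j")]))
  }
  en <- edges(narrow); ew <- edges(wide)
  if (!is.null(en)) {
    expect_true(all(paste(en$resno_i, en$resno_j) %in%
                      paste(ew$resno_i, ew$resno_j)))
  }
  ## every reported pair distance recomputes into its declared band
  for (cl in wide$clusters) {
    for (i in seq_len(nrow(cl$pairs))) {
      p <- cl$pairs[i, ]
      t1 <- charged_group_centroid(cloud$model, chain = p$chain_i,
                                   resno = p$resno_i)$coord
      t2 <- charged_group_centroid(cloud$model, chain = p$chain_j,
                                   resno = p$resno_j)$coord
      d <- sqrt(sum((t1 - t2)^2))
      expect_equal(d, p$dist, tolerance = 1e-9)
      expect_true(d >= 5 && d <= 10)
    }
  }
})

test_that("completion targets honour exposure and the anchor minimum", {
  fx <- generate_fixture(seed = 21)
  surf <- surface_profile(fx$model)
  tg <- find_completion_targets(fx$model, surf)
  ci <- fx$truth$candidate$resno
  expect_true(ci %in% tg$resno)
  row <- tg[tg$resno == ci, ]
  expect_equal(row$n_anchors, 2)
  expect_equal(sort(row$anchors[[1]]$resno), sort(fx$truth$anchors$resno))

  ## buried candidate disappears
  fb <- generate_fixture(seed = 21, candidate_buried = TRUE)
  sb <- surface_profile(fb$model)
  tb <- find_completion_targets(fb$model, sb)
  expect_false(fb$truth$candidate$resno %in%
                 tb$resno[tb$chain == "A"])

  ## a lone anchor is reachable with min_anchors = 1
  lone <- site_cloud(rbind(c(0, 0, 0)))
  m <- lone$model
  ## add a Ser whose projected tip lands ~7 A from the Lys tip
  m$residues <- rbind(m$residues,
                      data.frame(chain = "A", resno = 2L, aa = "S",
                                 modeled = TRUE))
  m$atoms <- rbind(m$atoms, data.frame(
    chain = "A", resno = 2L, elety = c("CA", "CB"),
    x = c(12.5, 11.5), y = 0, z = 0))
  surf <- rbind(lone$surface,
                data.frame(chain = "A", resno = 2L, aa = "S",
                           modeled = TRUE, exposed = TRUE,
                           rel_sasa = 1))
  expect_equal(nrow(find_completion_targets(m, surf, min_anchors = 2)), 0)
  t1 <- find_completion_targets(m, surf, min_anchors = 1)
  expect_equal(t1$resno, 2)
  expect_equal(t1$n_anchors, 1)
  expect_equal(t1$anchors[[1]]$dist, 7, tolerance = 1e-9)
})
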