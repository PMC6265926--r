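test_that("lattice adjacency has the expected geometry", {
  g1 <- make_lattice_adjacency(1, 1)
  expect_equal(n_regions(g1), 1L)
  expect_equal(lengths(g1$neighbors), c(`1` = 0L))

  g <- make_lattice_adjacency(5, 6)
  expect_equal(n_regions(g), 30L)
  corners <- c(1L, 6L, 25L, 30L)
  expect_equal(unname(lengths(g$neighbors)[corners]), rep(2L, 4))

  # edge-count oracle: enumerate all region pairs and test rook adjacency
  coords <- cbind(row = (0:29) %/% 6, col = (0:29) %% 6)
  brute_edges <- 0L
  for (i in 1:29) for (j in (i + 1):30) {
    if (sum(abs(coords[i, ] - coords[j, ])) == 1L) brute_edges <- brute_edges + 1L
  }
  expect_equal(brute_edges, 5 * (6 - 1) + 6 * (5 - 1))  # 49
  expect_equal(sum(lengths(g$neighbors)) / 2, brute_edges)

  expect_error(make_lattice_adjacency(0, 3), "rows")
})

test_that("graph files round-trip and asymmetry is rejected", {
  tmp <- withr::local_tempfile(fileext = ".gra")
  writeLines(c("3", "1", "1", "2", "2", "2", "1 3", "3", "1", "2"), tmp)
  g <- read_graph_file(tmp)
  expect_equal(g$neighbors, list(`1` = 2L, `2` = c(1L, 3L), `3` = 2L))

  out <- withr::local_tempfile(fileext = ".gra")
  g2 <- make_lattice_adjacency(4, 5)
  write_graph_file(g2, out)
  g2b <- read_graph_file(out)
  expect_equal(g2b$neighbors, g2$neighbors)
  expect_equal(g2b$region_ids, g2$region_ids)

  bad <- withr::local_tempfile(fileext = ".gra")
  writeLines(c("2", "1", "1", "2", "2", "0", ""), bad)
  expect_error(read_graph_file(bad), "asymmetric.*1.*2")

  dup <- withr::local_tempfile(fileext = ".gra")
  writeLines(c("2", "1", "0", "", "1", "0", ""), dup)
  expect_error(read_graph_file(dup), "duplicate")
})

test_that("self-loops and unknown neighbors are rejected", {
  expect_error(adjacency_graph(list(`1` = 1L)), "self-loop")
  expect_error(adjacency_graph(list(`1` = 9L)), "unknown")
})

test_that("connected components agree with a transitive-closure oracle", {
  expect_equal(unname(unique(connected_components(make_lattice_adjacency(5, 6)))), 1L)

  two_paths <- adjacency_graph(list(`1` = 2L, `2` = 1L, `3` = 4L, `4` = 3L))
  expect_equal(length(unique(connected_components(two_paths))), 2L)

  # random 30-node graph vs boolean reachability closure
  set.seed(42)
  d <- 30L
  a <- matrix(0L, d, d)
  for (k in 1:25) {
    ij <- sample.int(d, 2)
    a[ij[1], ij[2]] <- a[ij[2], ij[1]] <- 1L
  }
  nb <- lapply(seq_len(d), function(i) which(a[i, ] == 1L))
  names(nb) <- seq_len(d)
  g <- adjacency_graph(nb)
  reach <- a == 1L | diag(d) == 1
  for (step in seq_len(d)) reach <- reach | (reach %*% reach) > 0
  oracle <- match(apply(reach, 1, function(r) paste(which(r), collapse = ",")),
                  unique(apply(reach, 1, function(r) paste(which(r), collapse = ","))))
  comp <- unname(connected_components(g))
  # same partition: labels agree up to renaming
  expect_equal(length(unique(comp)), length(unique(oracle)))
  expect_true(all(tapply(oracle, comp, function(v) length(unique(v))) == 1L))
})

test_that("ICAR precision has degree diagonal, -1 neighbors, zero row sums", {
  q <- icar_precision(path_graph(3))
  expect_equal(unname(q), rbind(c(1, -1, 0), c(-1, 2, -1), c(0, -1, 1)))

  g <- make_lattice_adjacency(5, 6)
  q <- icar_precision(g)
  expect_equal(unname(rowSums(q)), rep(0, 30))
  ev <- eigen(q, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(abs(ev) < 1e-9), 1L)  # exactly one zero eigenvalue
})

test_that("pairwise-difference identity and rank hold on assorted graphs", {
  set.seed(7)
  graphs <- list(path_graph(5), make_lattice_adjacency(3, 4),
                 adjacency_graph(list(`1` = 2L, `2` = 1L, `3` = 4L, `4` = 3L)))
  for (g in graphs) {
    q <- icar_precision(g)
    f <- rnorm(n_regions(g))
    pairs <- 0
    ids <- g$region_ids
    for (j in seq_along(ids)) {
      for (k in g$neighbors[[j]]) {
        if (k > ids[j]) pairs <- pairs + (f[j] - f[match(k, ids)])^2
      }
    }
    expect_equal(drop(t(f) %*% q %*% f), pairs, tolerance = 1e-12)
    ncomp <- length(unique(connected_components(g)))
    expect_equal(qr(q)$rank, n_regions(g) - ncomp)
  }
})
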