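toy_atoms <- function() {
  ## five carbon atoms forming a wall fragment near the attachment
  data.frame(x = c(6, 6, 6, -6, 0), y = c(0, 4, -4, 0, 7),
             z = c(0, 0, 0, 0, 0), element = "C")
}

test_that("free space gives a symmetric cloud around the attachment", {
  cl <- av1_cloud(data.frame(x = numeric(0), y = numeric(0),
                             z = numeric(0)),
                  attachment = c(0, 0, 0),
                  params = dye_parameters(linker_length = 8), spacing = 1)
  expect_gt(cl$n_points, 100)
  expect_equal(unname(cl$mean_position), c(0, 0, 0), tolerance = 1e-9)
  rad <- sqrt(rowSums(cl$points^2))
  expect_lte(max(rad), 8 + 1e-9)
})

test_that("a caged attachment is a buried site", {
  shell <- expand.grid(x = c(-2, 0, 2), y = c(-2, 0, 2), z = c(-2, 0, 2))
  shell <- shell[!(shell$x == 0 & shell$y == 0 & shell$z == 0), ]
  shell$element <- "C"
  expect_error(av1_cloud(shell, c(0, 0, 0), dye_parameters(), spacing = 1),
               "buried site")
})

test_that("geodesic linker paths match an independent graph oracle", {
  skip_if_not_installed("igraph")
  atoms <- toy_atoms()
  prm <- dye_parameters(linker_length = 7, linker_width = 3,
                        dye_radius = 1.5)
  cl <- av1_cloud(atoms, c(0, 0, 0), prm, spacing = 1)

  ## independent oracle: explicit voxel graph + igraph shortest paths
  reach <- prm$linker_length + prm$dye_radius
  ax <- seq(-ceiling(reach), ceiling(reach), by = 1)
  grid <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  vdw <- 1.7
  clear <- rep(Inf, nrow(grid))
  for (i in seq_len(nrow(atoms)))
    clear <- pmin(clear, sqrt(colSums((t(grid) -
      as.numeric(atoms[i, 1:3]))^2)) - vdw)
  free <- clear >= prm$linker_width / 2
  src <- which(grid[, 1] == 0 & grid[, 2] == 0 & grid[, 3] == 0)
  free[src] <- TRUE
  idx_free <- which(free)
  key <- match(seq_len(nrow(grid)), idx_free)
  edges <- c(); wts <- c()
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off <- off[rowSums(abs(off)) > 0, ]
  n_ax <- length(ax)
  coord_to_lin <- function(m) (m[, 3] - 1) * n_ax^2 + (m[, 2] - 1) * n_ax + m[, 1]
  pos <- cbind(match(grid[idx_free, 1], ax), match(grid[idx_free, 2], ax),
               match(grid[idx_free, 3], ax))
  for (k in seq_len(nrow(off))) {
    np <- sweep(pos, 2, off[k, ], "+")
    ok <- np[, 1] >= 1 & np[, 1] <= n_ax & np[, 2] >= 1 & np[, 2] <= n_ax &
      np[, 3] >= 1 & np[, 3] <= n_ax
    lin <- coord_to_lin(np[ok, , drop = FALSE])
    tgt <- key[lin]
    src_i <- seq_along(idx_free)[ok]
    keep <- !is.na(tgt)
    edges <- c(edges, rbind(src_i[keep], tgt[keep]))
    wts <- c(wts, rep(sqrt(sum(off[k, ]^2)), sum(keep)))
  }
  g <- igraph::make_graph(edges, n = length(idx_free), directed = FALSE)
  d <- igraph::distances(g, v = match(src, idx_free), weights = wts)[1, ]
  allowed_oracle <- idx_free[d <= prm$linker_length &
                               clear[idx_free] >= prm$dye_radius]
  pts_oracle <- grid[allowed_oracle, , drop = FALSE]
  ## set equality with the package cloud
  a <- apply(round(cl$points, 6), 1, paste, collapse = ",")
  b <- apply(round(pts_oracle, 6), 1, paste, collapse = ",")
  expect_setequal(a, b)
})

test_that("the cloud shrinks monotonically with the linker length", {
  atoms <- toy_atoms()
  keyfun <- function(cl) apply(cl$points, 1, paste, collapse = ",")
  c_long <- av1_cloud(atoms, c(0, 0, 0),
                      dye_parameters(linker_length = 9), spacing = 1)
  c_short <- av1_cloud(atoms, c(0, 0, 0),
                       dye_parameters(linker_length = 6), spacing = 1)
  expect_true(all(keyfun(c_short) %in% keyfun(c_long)))
})

test_that("FRET observables from clouds: limits and Jensen ordering", {
  one_pt <- function(p) structure(list(points = matrix(p, 1, 3,
                                                       dimnames = list(NULL, c("x", "y", "z"))),
                                       mean_position = p, spacing = 1,
                                       attachment = p, n_points = 1),
                                  class = "av_cloud")
  a <- one_pt(c(0, 0, 0)); b <- one_pt(c(40, 0, 0))
  r <- av_fret_distance(a, b, R0 = 62, n_pairs = 1e3)
  expect_equal(r$R_mean, 40)
  expect_equal(r$R_mp, 40)
  expect_equal(r$E_mean, e_from_r(40, 62))

  cl <- av1_cloud(data.frame(x = numeric(0), y = numeric(0),
                             z = numeric(0)), c(0, 0, 0),
                  dye_parameters(linker_length = 8), spacing = 1)
  same <- av_fret_distance(cl, cl, n_pairs = 2e4)
  expect_equal(same$R_mp, 0)
  expect_gt(same$R_mean, 0)

  ## separated extended clouds: E-averaged distance below the mean
  ## distance, both within the geometric bracket
  big <- av1_cloud(data.frame(x = numeric(0), y = numeric(0),
                              z = numeric(0)), c(0, 0, 0),
                   dye_parameters(linker_length = 20), spacing = 1)
  big2 <- av1_cloud(data.frame(x = numeric(0), y = numeric(0),
                               z = numeric(0)), c(48, 0, 0),
                    dye_parameters(linker_length = 20), spacing = 1)
  sep <- av_fret_distance(big, big2, R0 = 62, n_pairs = 5e4, seed = 7)
  ## the E-averaged apparent distance differs from the plain mean
  ## (Jensen bias through the Forster curve) but stays within a few
  ## Angstrom of it for clouds of this extent
  expect_lt(abs(sep$R_E - sep$R_mean), 5)
  expect_gt(sep$R_mean, 28)
  expect_lt(sep$R_mean, 68)
  expect_gte(sep$R_mean, sep$R_mp - 1e-9)
})

test_that("grid refinement changes the mean distance by less than 1%", {
  atoms <- toy_atoms()
  prm <- dye_parameters(linker_length = 7)
  c1 <- av1_cloud(atoms, c(0, 0, 0), prm, spacing = 1)
  c05 <- av1_cloud(atoms, c(0, 0, 0), prm, spacing = 0.5)
  other1 <- av1_cloud(atoms, c(22, 18, 0), prm, spacing = 1)
  other05 <- av1_cloud(atoms, c(22, 18, 0), prm, spacing = 0.5)
  r1 <- av_fret_distance(c1, other1, n_pairs = 2e5, seed = 1)$R_mean
  r05 <- av_fret_distance(c05, other05, n_pairs = 2e5, seed = 1)$R_mean
  expect_lt(abs(r1 - r05) / r05, 0.01)
})
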