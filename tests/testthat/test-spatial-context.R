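# Neighbourhood index, hexagonal binning, background GMM and offsets.

test_that("radius neighbourhoods match brute-force pairwise distances", {
  cells <- tibble::tibble(cell_id = c("a", "b", "c"), x = c(0, 30, 100), y = 0)
  nb <- neighbor_index(cells, radius = 50)
  expect_equal(nb$neighbors, list(2L, 1L, integer(0)))

  # single cell has no neighbours at any radius
  nb1 <- neighbor_index(cells[1, ], radius = 1e6)
  expect_equal(nb1$neighbors, list(integer(0)))

  # default radius is 50 um
  expect_equal(formals(neighbor_index)$radius, 50)

  # boundary at exactly d is inclusive
  two <- tibble::tibble(cell_id = c("p", "q"), x = c(0, 50), y = 0)
  expect_equal(neighbor_index(two, 50)$neighbors, list(2L, 1L))

  # random point sets against the O(n^2) definition
  for (s in 1:25) {
    cells <- toy_cells(40, seed = s, extent = 200)
    nb <- neighbor_index(cells, radius = 35)
    d <- as.matrix(dist(cbind(cells$x, cells$y)))
    for (i in seq_len(40)) {
      expect_identical(nb$neighbors[[i]],
                       sort(setdiff(which(d[i, ] <= 35), i)))
    }
  }
})

test_that("neighbourhood relation is symmetric and never self-referential", {
  for (s in 1:50) {
    cells <- toy_cells(60, seed = 100 + s, extent = 300)
    nb <- neighbor_index(cells, radius = 40)
    adj <- nb$adjacency
    expect_true(Matrix::isSymmetric(adj))
    expect_true(all(Matrix::diag(adj) == 0))
  }
})

test_that("non-finite coordinates are rejected naming the cell", {
  cells <- tibble::tibble(cell_id = c("ok", "bad"), x = c(0, NaN), y = c(0, 1))
  expect_error(neighbor_index(cells, 50), "bad",
               class = "istclean_validation_error")
})

test_that("hexbinning conserves transcripts and approximates the target bin count", {
  # all transcripts in one hexagon
  tx <- tibble::tibble(x = c(0, 1, 2, 1.5), y = c(0, 1, 0.5, 0.2), gene = "g")
  tx <- rbind(tx, tibble::tibble(x = 500, y = 500, gene = "g")) # widen bbox
  g <- hexbin_transcripts(tx, n_bins = 50)
  expect_equal(sum(g$bins$total), 5)
  expect_true(all(g$bins$total %in% c(0, 1, 4)))

  # default target is 200 bins
  expect_equal(formals(hexbin_transcripts)$n_bins, 200)

  # geometric oracle: square extent, realised count near the target and
  # total hexagon area close to the bounding-box area
  tx <- withr::with_seed(7, tibble::tibble(
    x = runif(20000, 0, 1000), y = runif(20000, 0, 1000), gene = "g"
  ))
  tx$x[1:2] <- c(0, 1000)
  tx$y[1:2] <- c(0, 1000)
  g <- hexbin_transcripts(tx, n_bins = 200)
  expect_gte(nrow(g$bins), 160)
  expect_lte(nrow(g$bins), 240)
  expect_lt(abs(nrow(g$bins) * g$area - 1e6) / 1e6, 0.25)
  expect_equal(sum(g$bins$total), 20000)
  expect_equal(g$area, 1.5 * sqrt(3) * g$circumradius^2)

  # each transcript in exactly one bin: per-gene counts sum to totals
  expect_equal(as.numeric(Matrix::rowSums(g$gene_counts)), g$bins$total)
})

test_that("degenerate transcript clouds are rejected with advice", {
  tx <- tibble::tibble(x = rep(5, 10), y = rep(5, 10), gene = "g")
  expect_error(hexbin_transcripts(tx), "background",
               class = "istclean_validation_error")
})

test_that("background GMM separates clusters like the exhaustive ML partition", {
  totals <- c(10, 12, 11, 9, 100, 105, 98, 102)
  fit <- fit_background_gmm(totals)
  expect_equal(fit$background_bins, 1:4)
  expect_equal(fit$mu[fit$background_component], 10.5, tolerance = 0.01)
  expect_equal(sort(exhaustive_gmm_partition(totals)), sort(fit$background_bins))

  # responsibilities are a proper posterior
  expect_equal(rowSums(fit$responsibilities), rep(1, 8), tolerance = 1e-12)

  # swapped component initialisation yields the same background set
  init1 <- list(w = c(0.5, 0.5), mu = c(10, 100), sigma2 = c(5, 5))
  init2 <- list(w = c(0.5, 0.5), mu = c(100, 10), sigma2 = c(5, 5))
  f1 <- fit_background_gmm(totals, init = init1)
  f2 <- fit_background_gmm(totals, init = init2)
  expect_equal(sort(f1$background_bins), sort(f2$background_bins))
  expect_equal(sort(f1$mu), sort(f2$mu), tolerance = 1e-6)
})

test_that("single-Gaussian input keeps both components near the sample mean", {
  totals <- withr::with_seed(3, rnorm(200, mean = 50, sd = 5))
  fit <- fit_background_gmm(totals)
  expect_true(all(abs(fit$mu - mean(totals)) < 3 * sd(totals)))
  expect_equal(fit$background_component, which.min(fit$mu))
})

test_that("background GMM agrees with an independent mixture implementation", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  totals <- withr::with_seed(11, c(rnorm(60, 20, 4), rnorm(40, 90, 8)))
  fit <- fit_background_gmm(totals)
  mc <- mclust::Mclust(totals, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(fit$mu), sort(as.numeric(mc$parameters$mean)),
               tolerance = 0.05)
})

test_that("zero-variance bin totals are a validation error", {
  expect_error(fit_background_gmm(rep(5, 10)), "variance",
               class = "istclean_validation_error")
  expect_error(fit_background_gmm(c(1, 2)), "at least 4",
               class = "istclean_validation_error")
})

test_that("background profile applies the disc-to-bin area scaling", {
  # two background bins with gene counts 2 and 4; A = pi * 50^2 makes the
  # scale factor exactly 1, so the profile is the raw mean 3
  grid <- structure(list(
    bins = tibble::tibble(bin = c("a", "b", "c"), q = 0:2, r = 0L,
                          x = 0, y = 0, total = c(6, 5, 100)),
    gene_counts = Matrix::sparseMatrix(
      i = c(1, 2, 3), j = c(1, 1, 1), x = c(2, 4, 100),
      dims = c(3, 1), dimnames = list(c("a", "b", "c"), "g1")
    ),
    circumradius = sqrt(pi * 50^2 / (1.5 * sqrt(3))),
    area = pi * 50^2,
    origin = c(x = 0, y = 0)
  ), class = "hexbin_grid")
  gmm <- structure(list(
    background_bins = 1:2, background_component = 1L,
    mu = c(5.5, 100), w = 2 / 3
  ), class = "background_gmm")

  prof <- background_profile(grid, gmm, radius = 50)
  expect_equal(prof$x_b, 3)

  # doubling the bin area halves the profile (linearity in 1/A)
  grid2 <- grid
  grid2$area <- 2 * pi * 50^2
  expect_equal(background_profile(grid2, gmm, radius = 50)$x_b, 1.5)

  # gene absent from all background bins stays 0
  grid3 <- grid
  grid3$gene_counts <- Matrix::sparseMatrix(
    i = 3, j = 1, x = 100, dims = c(3, 1),
    dimnames = list(c("a", "b", "c"), "g1")
  )
  expect_equal(background_profile(grid3, gmm, radius = 50)$x_b, 0)

  # empty background set is an error advising disable
  gmm_empty <- structure(list(background_bins = integer(0)),
                         class = "background_gmm")
  expect_error(background_profile(grid, gmm_empty, 50), "disable",
               class = "istclean_validation_error")
})

test_that("offsets equal background plus neighbour sums", {
  cells <- tibble::tibble(cell_id = c("A", "B", "C"), x = c(0, 30, 100), y = 0)
  counts <- matrix(c(5, 7, 2), ncol = 1,
                   dimnames = list(cells$cell_id, "g1"))
  nb <- neighbor_index(cells, 50)
  bg <- tibble::tibble(gene = "g1", x_b = 1)
  xp <- compute_offsets(counts, nb, bg)
  expect_equal(as.numeric(xp), c(8, 6, 1))

  # isolated cell without background: all-zero offsets, with a warning
  iso <- tibble::tibble(cell_id = "A", x = 0, y = 0)
  expect_warning(
    xp0 <- compute_offsets(matrix(3, 1, 1, dimnames = list("A", "g1")),
                           neighbor_index(iso, 50), NULL),
    "background"
  )
  expect_equal(as.numeric(xp0), 0)
})

test_that("offsets match a brute-force triple loop and permute with cells", {
  for (s in 1:5) {
    cells <- toy_cells(50, seed = 200 + s, extent = 300)
    counts <- withr::with_seed(s, matrix(rpois(50 * 20, 2), 50, 20,
      dimnames = list(cells$cell_id, paste0("g", 1:20))
    ))
    x_b <- withr::with_seed(s, runif(20, 0, 2))
    bg <- tibble::tibble(gene = paste0("g", 1:20), x_b = x_b)
    nb <- neighbor_index(cells, 60)
    xp <- compute_offsets(counts, nb, bg)
    expect_equal(xp, brute_force_offsets(counts, cells, 60, x_b))
    expect_true(all(sweep(xp, 2, x_b, `-`) >= -1e-12))
  }

  # permuting cell order permutes offset rows identically
  cells <- toy_cells(30, seed = 9, extent = 150)
  counts <- withr::with_seed(9, matrix(rpois(30 * 5, 3), 30, 5,
    dimnames = list(cells$cell_id, paste0("g", 1:5))
  ))
  perm <- withr::with_seed(10, sample(30))
  xp <- suppressWarnings(compute_offsets(counts, neighbor_index(cells, 40), NULL))
  xp_perm <- suppressWarnings(
    compute_offsets(counts[perm, ], neighbor_index(cells[perm, ], 40), NULL)
  )
  expect_equal(xp_perm, xp[perm, ])
})

test_that("offset computation validates index consistency", {
  cells <- toy_cells(5)
  nb <- neighbor_index(cells, 50)
  counts <- matrix(0, 4, 2)
  expect_error(suppressWarnings(compute_offsets(counts, nb, NULL)),
               class = "istclean_validation_error")
})
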