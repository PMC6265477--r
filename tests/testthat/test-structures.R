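test_that("minimal PDB round trip preserves atoms and names", {
  m <- synthetic_site_model()
  expect_s3_class(m, "structure_model")
  expect_equal(nrow(m$atoms), 9)
  expect_true(all(c("OG", "O1P", "O2P") %in% m$atoms$elety))
  expect_error(read_structure(tempfile(fileext = ".pdb")), "no such file")
})

test_that("contact distances in the synthetic active site read correctly", {
  m <- synthetic_site_model()
  d1 <- measure_distance(m, "A:210:OG", "A:301:O1P")
  expect_equal(as.numeric(d1), 2.7)
  d2 <- measure_distance(m, "A:211:OG", "A:301:O1P")
  expect_equal(as.numeric(d2), 3.7)
  # symmetric in its arguments
  expect_equal(as.numeric(measure_distance(m, "A:301:O1P", "A:210:OG")), 2.7)
  # full precision retained alongside the display rounding
  expect_equal(attr(d1, "exact"), 2.7, tolerance = 1e-6)
  expect_error(measure_distance(m, "A:210:OG", "A:999:XX"), "not found")
})

test_that("hydrogen bond detection applies the distance bands", {
  m <- synthetic_site_model()
  hb <- detect_hbonds(m)
  key <- paste(hb$donor, hb$acceptor)
  # 2.9 A backbone pair: detected, not weak
  i <- grepl("118:N", key) & grepl("120:O", key)
  expect_true(any(i))
  expect_false(hb$weak[i])
  # 2.7 A serine-phosphate: detected, not weak
  j <- grepl("210:OG", key) & grepl("301:O1P", key)
  expect_true(any(j))
  expect_false(hb$weak[j])
  # 3.3 A pair flagged weak
  k <- grepl("301:O2P", key) & grepl("118:N", key)
  expect_true(any(k))
  expect_true(all(hb$weak[k]))
  # 3.7 A pair not reported at all
  expect_false(any(grepl("211:OG", key) & grepl("301:O1P", key)))
  expect_true(all(hb$distance <= 3.5))
})

test_that("glycosidic chi classification follows the syn window", {
  # planar trans arrangement: chi ~ 180 -> anti
  m180 <- chi_nucleotide_model(180)
  g <- glycosidic_chi(m180, "B:5")
  expect_equal(abs(g$chi), 180, tolerance = 1)
  expect_equal(g$conformation, "anti")
  # constructed 45 degree torsion -> syn
  m45 <- chi_nucleotide_model(45)
  g45 <- glycosidic_chi(m45, "B:5")
  expect_equal(abs(g45$chi), 45, tolerance = 1)
  expect_equal(g45$conformation, "syn")
  # boundary behaviour and pyrimidine atom set
  mpy <- chi_nucleotide_model(-120, purine = FALSE)
  gpy <- glycosidic_chi(mpy, "B:5")
  expect_equal(gpy$conformation, "anti")
  expect_error(glycosidic_chi(m45, "B:9"), "not found")
})

test_that("chi torsion agrees with an independent dihedral implementation", {
  for (chi in c(-150, -60, 10, 45, 120)) {
    m <- chi_nucleotide_model(chi)
    # same coordinates through both implementations (bio3d's torsion sign
    # convention is mirrored, so compare magnitudes)
    ord <- match(c("O4'", "C1'", "N9", "C4"), m$atoms$elety)
    xyz <- as.numeric(t(as.matrix(m$atoms[ord, c("x", "y", "z")])))
    tor <- as.numeric(bio3d::torsion.xyz(xyz))[1]
    ours <- glycosidic_chi(m, "B:5")$chi
    expect_equal(abs(ours), abs(tor), tolerance = 1e-6)
  }
})

test_that("altloc resolution keeps the highest-occupancy conformer", {
  path <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  OG ASER A 210       0.000   0.000   0.000  0.30 10.00           O",
    "ATOM      2  OG BSER A 210       1.000   0.000   0.000  0.70 10.00           O",
    "END"), path)
  m <- read_structure(path)
  expect_equal(nrow(m$atoms), 1)
  expect_equal(m$atoms$x, 1.0)
})

test_that("Kabsch RMSD: exact zeros, rigid-motion invariance, oracle match", {
  set.seed(14)
  A <- matrix(rnorm(30, sd = 3), 10, 3)
  expect_equal(kabsch_rmsd(A, A), 0, tolerance = 1e-12)
  moved <- rigid_motion(A, seed = 99)
  expect_lt(kabsch_rmsd(A, moved), 1e-9)
  expect_lt(kabsch_rmsd(moved, A), 1e-9)
  # independent oracle: direct minimisation over axis-angle rotations
  B <- A + matrix(rnorm(30, sd = 0.5), 10, 3)
  rmsd_of <- function(par) {
    th <- sqrt(sum(par[1:3]^2))
    ax <- if (th > 0) par[1:3] / th else c(1, 0, 0)
    K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
    R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
    Ac <- sweep(A, 2, colMeans(A)); Bc <- sweep(B, 2, colMeans(B))
    sqrt(mean(rowSums((Ac - Bc %*% R)^2)))
  }
  set.seed(15)
  best <- Inf
  for (i in 1:25) {
    r <- stats::optim(rnorm(3), rmsd_of, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
    best <- min(best, r$value)
  }
  expect_equal(kabsch_rmsd(A, B), best, tolerance = 1e-3)
  expect_lte(kabsch_rmsd(A, B), best + 1e-9) # ours is the optimum
  expect_error(kabsch_rmsd(A[1:2, ], A[1:2, ]), "3 points")
  expect_error(kabsch_rmsd(A, A[1:5, ]), "paired")
})
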