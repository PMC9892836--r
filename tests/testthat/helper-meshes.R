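# Shared fixture geometry, built once per test run.

# a coarse reference leg (fast; landmarks and zones are resolution-invariant)
test_leg <- local({
  leg <- NULL
  function() {
    if (is.null(leg)) leg <<- build_reference_leg(n_circ = 16, n_axial = 1)
    leg
  }
})

# flat rectangular patch in the z = 0 plane, triangulated on a unit grid
planar_patch <- function(nx = 10, ny = 6) {
  gx <- seq(0, nx, 1); gy <- seq(0, ny, 1)
  pv <- cbind(as.matrix(expand.grid(x = gx, y = gy)), 0)
  w <- length(gx)
  id <- function(i, j) (j - 1) * w + i
  pf <- list()
  for (j in seq_len(length(gy) - 1)) {
    for (i in seq_len(w - 1)) {
      pf[[length(pf) + 1]] <- rbind(c(id(i, j), id(i + 1, j), id(i, j + 1)),
                                    c(id(i + 1, j), id(i + 1, j + 1),
                                      id(i, j + 1)))
    }
  }
  surface_mesh(pv, do.call(rbind, pf))
}

# open cylinder of radius r, height h
cylinder_mesh <- function(r = 5, h = 10, n_circ = 64, n_axial = 10) {
  z <- seq(0, h, length.out = n_axial + 1)
  ph <- (seq_len(n_circ) - 1) * 2 * pi / n_circ
  verts <- do.call(rbind, lapply(z, function(zz)
    cbind(r * cos(ph), r * sin(ph), zz)))
  fcs <- list()
  nxt <- c(seq_len(n_circ)[-1], 1)
  for (i in seq_len(n_axial)) {
    lo <- (i - 1) * n_circ; hi <- i * n_circ
    a <- lo + seq_len(n_circ); b <- lo + nxt
    c_ <- hi + seq_len(n_circ); d <- hi + nxt
    fcs[[i]] <- rbind(cbind(a, b, c_), cbind(b, d, c_))
  }
  surface_mesh(verts, do.call(rbind, fcs))
}

# anchor a point at a given vertex of a mesh
anchor_at_vertex <- function(mesh, v) {
  f <- which(mesh$faces[, 1] == v | mesh$faces[, 2] == v |
               mesh$faces[, 3] == v)[1]
  b <- rep(0, 3)
  b[which(mesh$faces[f, ] == v)] <- 1
  anchored_points(mesh, f, matrix(b, 1))
}

# build per-patient concordance rows from category counts
make_scores <- function(leg_counts, foot_counts) {
  cat_leg <- rep(c("full", "partial", "none"), leg_counts)
  cat_foot <- rep(c("full", "partial", "none"), foot_counts)
  data.frame(category = c(cat_leg, cat_foot),
             site = rep(c("lower_leg", "foot"),
                        c(length(cat_leg), length(cat_foot))),
             stringsAsFactors = FALSE)
}
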