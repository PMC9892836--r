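#' Geodesic graph over a triangle mesh
#'
#' Builds the weighted graphs used to approximate skin-surface (geodesic)
#' distances.  For every level l = 0..refinement, nodes are the mesh
#' vertices plus Steiner points at dyadic positions along every edge
#' (level l inserts 2^l - 1 points per edge), and every pair of nodes on
#' the boundary of a common face is joined by its straight-line segment,
#' which lies in that face's plane.  A distance query runs Dijkstra's
#' algorithm on each level and shortens every candidate path to the exact
#' geodesic of its crossing sequence (see [geodesic_distance()]); because
#' the dyadic node sets are nested, the candidate set grows with the
#' refinement level and the reported length is non-increasing in it.
#'
#' @param mesh a `surface_mesh`.
#' @param refinement maximal subdivision level (default 3, i.e. up to 7
#'   Steiner points per edge).
#' @return object of class `geodesic_graph`.
#' @export
geodesic_graph <- function(mesh, refinement = 3) {
  refinement <- as.integer(refinement)
  if (refinement < 0L) stop("refinement must be >= 0", call. = FALSE)
  v <- mesh$vertices
  f <- mesh$faces
  ed <- mesh_edges(mesh)
  n_v <- nrow(v)
  n_e <- nrow(ed)
  nf <- nrow(f)
  # map face -> its three undirected edge ids
  ekey <- ed[, 1L] + ed[, 2L] * (n_v + 1)
  fe <- function(i, j) {
    key <- pmin(i, j) + pmax(i, j) * (n_v + 1)
    match(key, ekey)
  }
  fedges <- cbind(fe(f[, 1L], f[, 2L]), fe(f[, 2L], f[, 3L]),
                  fe(f[, 3L], f[, 1L]))
  build_level <- function(k) {
    if (k > 0L) {
      tfrac <- seq_len(k) / (k + 1L)
      p1 <- v[ed[, 1L], , drop = FALSE]
      p2 <- v[ed[, 2L], , drop = FALSE]
      spts <- do.call(rbind, lapply(tfrac, function(t) p1 + t * (p2 - p1)))
      coords <- rbind(v, spts)
      # node ids of the Steiner points of edge e: n_v + (j-1)*n_e + e
      edge_nodes <- function(e) n_v + (seq_len(k) - 1L) * n_e + e
    } else {
      coords <- v
      edge_nodes <- function(e) integer(0)
    }
    face_nodes <- lapply(seq_len(nf), function(i) {
      c(f[i, ], edge_nodes(fedges[i, 1L]), edge_nodes(fedges[i, 2L]),
        edge_nodes(fedges[i, 3L]))
    })
    m <- 3L + 3L * k
    pairs <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
    from <- unlist(lapply(face_nodes, function(nd) nd[pairs[, 1L]]))
    to <- unlist(lapply(face_nodes, function(nd) nd[pairs[, 2L]]))
    a <- pmin(from, to); b <- pmax(from, to)
    keep <- !duplicated(a + b * (nrow(coords) + 1))
    a <- a[keep]; b <- b[keep]
    w <- sqrt(rowSums((coords[a, , drop = FALSE] -
                         coords[b, , drop = FALSE])^2))
    g <- igraph::make_empty_graph(n = nrow(coords), directed = FALSE)
    g <- igraph::add_edges(g, rbind(a, b), weight = w)
    list(graph = g, coords = coords, face_nodes = face_nodes, k = k)
  }
  levels <- lapply(0:refinement, function(l) build_level(2L^l - 1L))
  edge_faces <- split(rep(seq_len(nf), 3L),
                      factor(c(fedges), levels = seq_len(n_e)))
  vertex_faces <- split(rep(seq_len(nf), 3L),
                        factor(c(f), levels = seq_len(n_v)))
  vertex_edges <- split(rep(seq_len(n_e), 2L),
                        factor(c(ed), levels = seq_len(n_v)))
  structure(list(levels = levels, mesh = mesh, refinement = refinement,
                 edges = ed, n_vertices = n_v, n_edges = n_e,
                 face_edges = fedges, edge_faces = edge_faces,
                 vertex_faces = vertex_faces, vertex_edges = vertex_edges),
            class = "geodesic_graph")
}

#' @export
print.geodesic_graph <- function(x, ...) {
  top <- x$levels[[length(x$levels)]]
  cat(sprintf(
    "<geodesic_graph> refinement %d: %d nodes, %d edges at top level\n",
    x$refinement, igraph::vcount(top$graph), igraph::ecount(top$graph)))
  invisible(x)
}

as_anchor <- function(mesh, a) {
  if (is.data.frame(a)) a <- as.list(a[1L, ])
  if (is.null(a$face)) stop("point is not anchored on the surface (need ",
                            "face + barycentric coordinates)", call. = FALSE)
  bary <- if (!is.null(a$bary)) a$bary else c(a$b1, a$b2, a$b3)
  ap <- anchored_points(mesh, a$face, matrix(bary, 1L))
  list(face = ap$face, point = c(ap$x, ap$y, ap$z))
}

#' Skin-surface (geodesic) distance between two anchored points
#'
#' Approximates the shortest path along the mesh surface between two
#' surface-anchored points, the algorithmic analogue of a skin-surface
#' distance-measuring tool.  At every subdivision level both endpoints are
#' inserted as graph nodes connected to every node on their face's
#' boundary and Dijkstra's algorithm runs on that level's Steiner-point
#' graph; each candidate path is then iteratively shortened to the exact
#' geodesic of its crossing sequence (sliding crossing points along their
#' edges, unfolding vertex stars, dropping redundant points) and the
#' shortest result is returned.  The candidate sets are nested across
#' levels, so the length is non-increasing in the refinement level, and
#' the two endpoints are processed in a canonical order so the distance
#' is exactly symmetric in its arguments.
#'
#' @param x a `geodesic_graph`, or a `surface_mesh` (a graph is then built
#'   at the given refinement).
#' @param a,b anchored points: one-row data.frames with `face`, `b1`, `b2`,
#'   `b3` (as returned by [anchored_points()]), or lists with `face` and
#'   `bary`.
#' @param refinement used only when `x` is a mesh.
#' @return object of class `surface_path`: list with `points` (polyline
#'   along the surface, n x 3), `length` (cm), `graph_length` (the
#'   unshortened Dijkstra length at the top level), `level_lengths` (the
#'   reported length after each successive refinement level, non-
#'   increasing), `refinement`.
#' @examples
#' \donttest{
#' leg <- build_reference_leg(n_circ = 16, n_axial = 1)
#' gg <- geodesic_graph(leg, refinement = 2)
#' a <- anchored_points(leg, 1, matrix(c(1, 0, 0), 1))
#' b <- anchored_points(leg, 400, matrix(c(1, 0, 0), 1))
#' geodesic_distance(gg, a, b)$length
#' }
#' @export
geodesic_distance <- function(x, a, b, refinement = 3) {
  gg <- if (inherits(x, "geodesic_graph")) x else
    geodesic_graph(x, refinement)
  mesh <- gg$mesh
  pa <- as_anchor(mesh, a)
  pb <- as_anchor(mesh, b)
  # canonical argument order => exact symmetry
  key <- function(p) c(p$face, p$point)
  swapped <- FALSE
  ka <- key(pa); kb <- key(pb)
  cmp <- ka - kb
  nz <- which(cmp != 0)
  if (length(nz) && cmp[nz[1L]] > 0) {
    tmp <- pa; pa <- pb; pb <- tmp
    swapped <- TRUE
  }
  d_ab <- sqrt(sum((pa$point - pb$point)^2))
  if (pa$face == pb$face || d_ab == 0) {
    pts <- rbind(pa$point, pb$point)
    if (swapped) pts <- pts[2:1, , drop = FALSE]
    return(structure(list(points = pts, length = d_ab,
                          graph_length = d_ab,
                          level_lengths = rep(d_ab, gg$refinement + 1L),
                          refinement = gg$refinement),
                     class = "surface_path"))
  }
  best <- NULL
  graph_len_top <- NA_real_
  level_lengths <- numeric(0)
  for (lev in gg$levels) {
    na <- lev$face_nodes[[pa$face]]
    nb <- lev$face_nodes[[pb$face]]
    wa <- sqrt(rowSums(sweep(lev$coords[na, , drop = FALSE], 2L,
                             pa$point)^2))
    wb <- sqrt(rowSums(sweep(lev$coords[nb, , drop = FALSE], 2L,
                             pb$point)^2))
    n0 <- igraph::vcount(lev$graph)
    g2 <- igraph::add_vertices(lev$graph, 2L)
    src <- n0 + 1L; dst <- n0 + 2L
    g2 <- igraph::add_edges(g2, c(rbind(src, na), rbind(dst, nb)),
                            weight = c(wa, wb))
    sp <- igraph::shortest_paths(g2, from = src, to = dst, weights = NULL,
                                 output = "both")
    vpath <- as.integer(sp$vpath[[1L]])
    if (length(vpath) == 0L) {
      stop("no path between anchor faces (mesh disconnected?)",
           call. = FALSE)
    }
    graph_len <- sum(igraph::E(g2)$weight[as.integer(sp$epath[[1L]])])
    graph_len_top <- graph_len
    inner <- vpath[vpath <= n0]
    pts <- rbind(pa$point, lev$coords[inner, , drop = FALSE], pb$point)
    st <- straighten_path(gg, pts, inner, pa$face, pb$face, level_k = lev$k)
    st$len <- min(st$len, graph_len)
    if (is.null(best) || st$len < best$len) best <- st
    level_lengths <- c(level_lengths, best$len)
  }
  if (swapped) {
    best$pts <- best$pts[rev(seq_len(nrow(best$pts))), , drop = FALSE]
  }
  structure(list(points = unname(best$pts), length = best$len,
                 graph_length = graph_len_top,
                 level_lengths = level_lengths,
                 refinement = gg$refinement),
            class = "surface_path")
}

# Iterative shortening of a graph path toward the exact polyhedral
# geodesic.  The path is a list of surface points, each either an anchor
# (fixed endpoint), a point on a mesh edge, or a point on a mesh vertex.
# Three local moves repeat until the length converges:
#   slide  - an edge point moves along its edge to the local straight-line
#            (Snell) position between its neighbours; a point reaching an
#            edge endpoint becomes a vertex point;
#   escape - a vertex point whose unfolded star wedge between its
#            neighbours is flatter than pi is replaced by the exact
#            crossing points of the unfolded straight line with the star
#            edges (the classical funnel/unfolding step);
#   drop   - a point whose two neighbours share a carrier face is removed
#            (the shortcut segment lies inside that convex face).
# Every accepted move strictly shortens the path and keeps consecutive
# points on a common face, so the polyline stays on the surface.
straighten_path <- function(gg, pts, inner, face_a, face_b,
                            level_k = NULL, tol = 1e-12, max_sweep = 300L) {
  n <- nrow(pts)
  seg_len <- function(p, q) sqrt(sum((p - q)^2))
  if (n <= 2L) {
    len <- 0
    for (i in seq_len(n - 1L)) len <- len + seg_len(pts[i, ], pts[i + 1L, ])
    return(list(pts = pts, len = len))
  }
  vx <- gg$mesh$vertices
  n_v <- gg$n_vertices

  mk_state <- function(pos, kind, eid = NA_integer_, vid = NA_integer_,
                       faces = NULL) {
    list(pos = pos, kind = kind, eid = eid, vid = vid,
         faces = if (!is.null(faces)) faces else switch(kind,
           edge = gg$edge_faces[[eid]], vertex = gg$vertex_faces[[vid]]))
  }
  path <- vector("list", n)
  path[[1L]] <- mk_state(pts[1L, ], "anchor", faces = face_a)
  path[[n]] <- mk_state(pts[n, ], "anchor", faces = face_b)
  for (j in seq_along(inner)) {
    nd <- inner[j]
    if (nd > n_v) {
      eid <- (nd - n_v - 1L) %% gg$n_edges + 1L
      path[[j + 1L]] <- mk_state(pts[j + 1L, ], "edge", eid = eid)
    } else {
      path[[j + 1L]] <- mk_state(pts[j + 1L, ], "vertex", vid = nd)
    }
  }

  # optimum of |a-x| + |x-b| for x on segment (p1, p2); returns t in cm
  slide_opt <- function(a, b, p1, p2) {
    d <- p2 - p1
    L2 <- sum(d^2)
    if (L2 < 1e-24) return(list(t = 0, x = p1, L = 0))
    L <- sqrt(L2); dh <- d / L
    av <- a - p1; bv <- b - p1
    ta <- sum(av * dh); tb <- sum(bv * dh)
    ra <- sqrt(max(sum(av^2) - ta^2, 0))
    rb <- sqrt(max(sum(bv^2) - tb^2, 0))
    t <- if (ra + rb < 1e-14) (ta + tb) / 2 else
      (ta * rb + tb * ra) / (ra + rb)
    t <- min(max(t, 0), L)
    list(t = t, x = p1 + t * dh, L = L)
  }

  # the two edges of face f incident to vertex v
  v_edges_of_face <- function(f, v) {
    e3 <- gg$face_edges[f, ]
    e3[gg$edges[e3, 1L] == v | gg$edges[e3, 2L] == v]
  }
  other_endpoint <- function(e, v) {
    ends <- gg$edges[e, ]
    if (ends[1L] == v) ends[2L] else ends[1L]
  }
  # angle at v inside face f
  face_angle_at <- function(f, v) {
    es <- v_edges_of_face(f, v)
    u1 <- vx[other_endpoint(es[1L], v), ] - vx[v, ]
    u2 <- vx[other_endpoint(es[2L], v), ] - vx[v, ]
    acos(min(max(sum(u1 * u2) / sqrt(sum(u1^2) * sum(u2^2)), -1), 1))
  }
  angle_between <- function(u1, u2) {
    acos(min(max(sum(u1 * u2) / sqrt(sum(u1^2) * sum(u2^2)), -1), 1))
  }

  # Unfold the star of vertex v between neighbour points a and b.
  # Returns NULL (keep the vertex) or a list of edge states replacing it.
  escape_vertex <- function(v, a, b, faces_a, faces_b) {
    star <- gg$vertex_faces[[v]]
    f_start <- intersect(star, faces_a)
    f_end <- intersect(star, faces_b)
    if (!length(f_start) || !length(f_end)) return(NULL)
    f_start <- f_start[1L]; f_end <- f_end[1L]
    if (f_start == f_end) return(NULL)        # drop rule handles this
    av <- a - vx[v, ]; bv <- b - vx[v, ]
    ra <- sqrt(sum(av^2)); rb <- sqrt(sum(bv^2))
    if (ra < 1e-12 || rb < 1e-12) return(NULL)
    best <- NULL
    for (first_exit in v_edges_of_face(f_start, v)) {
      w <- local({
        cross <- integer(0)
        cums <- numeric(0)
        ang <- angle_between(av,
                             vx[other_endpoint(first_exit, v), ] - vx[v, ])
        e_in <- first_exit
        f <- f_start
        res <- NULL
        for (step in seq_len(length(star) + 1L)) {
          nxt_f <- setdiff(gg$edge_faces[[e_in]], f)
          if (!length(nxt_f)) break
          f <- nxt_f[1L]
          if (f == f_end) {
            ang_b <- angle_between(vx[other_endpoint(e_in, v), ] - vx[v, ],
                                   bv)
            res <- list(cross = c(cross, e_in), cum = c(cums, ang),
                        alpha = ang + ang_b)
            break
          }
          cross <- c(cross, e_in)
          cums <- c(cums, ang)
          e_out <- setdiff(v_edges_of_face(f, v), e_in)
          if (!length(e_out)) break
          ang <- ang + face_angle_at(f, v)
          e_in <- e_out[1L]
        }
        res
      })
      if (is.null(w)) next
      if (w$alpha < pi - 1e-12 &&
          (is.null(best) || w$alpha < best$alpha)) best <- w
    }
    if (is.null(best)) return(NULL)           # geodesic passes through v
    alpha <- best$alpha
    out <- vector("list", length(best$cross))
    for (i in seq_along(best$cross)) {
      e <- best$cross[i]
      ci <- best$cum[i]
      denom <- ra * sin(ci) + rb * sin(alpha - ci)
      r_i <- if (denom < 1e-14) 0 else ra * rb * sin(alpha) / denom
      u <- vx[other_endpoint(e, v), ] - vx[v, ]
      Lu <- sqrt(sum(u^2))
      r_i <- min(max(r_i, 1e-9), Lu - 1e-9)
      out[[i]] <- mk_state(vx[v, ] + (r_i / Lu) * u, "edge", eid = e)
    }
    out
  }

  total_len <- function(p) {
    s <- 0
    for (i in seq_len(length(p) - 1L)) {
      s <- s + seg_len(p[[i]]$pos, p[[i + 1L]]$pos)
    }
    s
  }

  prev_len <- total_len(path)
  for (sweep in seq_len(max_sweep)) {
    # drop pass
    i <- 2L
    while (i <= length(path) - 1L) {
      if (length(intersect(path[[i - 1L]]$faces, path[[i + 1L]]$faces))) {
        path[[i]] <- NULL
      } else {
        i <- i + 1L
      }
    }
    if (length(path) <= 2L) break
    # slide pass
    for (i in seq(2L, length(path) - 1L)) {
      st <- path[[i]]
      if (st$kind != "edge") next
      so <- slide_opt(path[[i - 1L]]$pos, path[[i + 1L]]$pos,
                      vx[gg$edges[st$eid, 1L], ], vx[gg$edges[st$eid, 2L], ])
      if (so$L == 0) next
      if (so$t < 1e-9) {
        path[[i]] <- mk_state(vx[gg$edges[st$eid, 1L], ], "vertex",
                              vid = gg$edges[st$eid, 1L])
      } else if (so$t > so$L - 1e-9) {
        path[[i]] <- mk_state(vx[gg$edges[st$eid, 2L], ], "vertex",
                              vid = gg$edges[st$eid, 2L])
      } else {
        path[[i]]$pos <- so$x
      }
    }
    # escape pass (may insert points; work right to left to keep indices)
    for (i in rev(seq(2L, length(path) - 1L))) {
      st <- path[[i]]
      if (st$kind != "vertex") next
      repl <- escape_vertex(st$vid, path[[i - 1L]]$pos, path[[i + 1L]]$pos,
                            path[[i - 1L]]$faces, path[[i + 1L]]$faces)
      if (is.null(repl)) next
      new_piece <- c(repl)
      cand <- c(path[seq_len(i - 1L)], new_piece,
                path[seq(i + 1L, length(path))])
      if (total_len(cand) < total_len(path) - 1e-13) path <- cand
    }
    cur_len <- total_len(path)
    if (prev_len - cur_len < tol) break
    prev_len <- cur_len
  }
  out <- do.call(rbind, lapply(path, function(s) s$pos))
  list(pts = out, len = total_len(path))
}

#' @export
print.surface_path <- function(x, ...) {
  cat(sprintf("<surface_path> length %.2f cm over %d segments (refinement %d)\n",
              x$length, nrow(x$points) - 1L, x$refinement))
  invisible(x)
}

#' Geodesic distances for a table of lesion pairs
#'
#' Convenience wrapper computing the primary-to-ITM surface distance for
#' every ITM of every patient in a mapped lesion table.
#'
#' @param gg a `geodesic_graph` over the reference surface.
#' @param mapped mapped lesion table (see [map_patient()]) with columns
#'   `patient_id`, `lesion_id`, `role`, `site`, `face`, `b1`, `b2`, `b3`.
#' @return data.frame `patient_id`, `lesion_id`, `site`, `distance_cm`.
#' @export
lesion_distances <- function(gg, mapped) {
  out <- list()
  for (pid in unique(mapped$patient_id)) {
    rows <- mapped[mapped$patient_id == pid, , drop = FALSE]
    prim <- rows[rows$role == "primary", , drop = FALSE]
    itms <- rows[rows$role == "itm", , drop = FALSE]
    if (nrow(prim) != 1L || nrow(itms) == 0L) next
    for (i in seq_len(nrow(itms))) {
      d <- geodesic_distance(gg, prim[1L, ], itms[i, ])
      out[[length(out) + 1L]] <- data.frame(
        patient_id = pid, lesion_id = itms$lesion_id[i],
        site = prim$site[1L], distance_cm = d$length,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(patient_id = character(), lesion_id = character(),
                      site = character(), distance_cm = numeric()))
  }
  do.call(rbind, out)
}

#' Summarize primary-to-ITM distances by site
#'
#' Per-site mean, median, minimum and maximum of the skin-surface
#' distances between primary melanoma and its in-transit metastases,
#' reported to 0.1 cm, plus a two-sided Mann-Whitney comparison of the
#' per-lesion distances between foot and lower leg.
#'
#' @param distances data.frame with columns `site` (`foot`/`lower_leg`) and
#'   `distance_cm` (e.g. from [lesion_distances()]).
#' @return list with `summary` (data.frame: site, n, mean, median, min,
#'   max) and `comparison` ([mw_test()] result, `NULL` if either site has
#'   fewer than 2 distances).
#' @export
distance_summary <- function(distances) {
  sites <- c("foot", "lower_leg")
  if (!all(distances$site %in% sites)) {
    stop("distance summary supports sites foot and lower_leg", call. = FALSE)
  }
  rows <- lapply(sites, function(s) {
    d <- distances$distance_cm[distances$site == s]
    if (length(d) == 0L) {
      stop("no distances for site ", s, call. = FALSE)
    }
    data.frame(site = s, n = length(d),
               mean = round_half_up(mean(d), 1),
               median = round_half_up(stats::median(d), 1),
               min = round_half_up(min(d), 1),
               max = round_half_up(max(d), 1), stringsAsFactors = FALSE)
  })
  smry <- do.call(rbind, rows)
  comparison <- NULL
  if (all(smry$n >= 2L)) {
    comparison <- mw_test(distances$distance_cm[distances$site == "foot"],
                          distances$distance_cm[distances$site == "lower_leg"])
  }
  list(summary = smry, comparison = comparison)
}
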