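## Gyral-net extraction and 3-hinge identification on a triangulated
## surface: altitude field, watershed crest segmentation, distance
## transform + tree marching skeletonization, and degree-3 joint detection.

#' Detection configuration
#'
#' @param level Altitude level cutting the gyral crest (mm); 0 keeps every
#'   vertex above the midsurface.
#' @param method Midsurface realization: \code{"smooth"} (Laplacian-smoothed
#'   copy, rigid-motion invariant) or \code{"plane"} (axis-aligned shortcut
#'   for simulated slabs).
#' @param smooth_length Physical smoothing length of the midsurface (mm);
#'   \code{NULL} uses a tenth of the surface bounding-box diagonal, which
#'   makes the midsurface invariant under uniform scaling and mesh
#'   subdivision.  The Laplacian iteration count follows from the diffusion
#'   scaling \eqn{n \approx (2 L_s / h)^2 / \lambda} with h the mean edge
#'   length.
#' @param lambda Laplacian smoothing step in (0, 1].
#' @param prune_frac Branches shorter than this fraction of their
#'   component's longest leaf branch are pruned from the skeleton.
#' @return An object of class \code{detect_config}.
#' @export
detect_config <- function(level = 0, method = c("smooth", "plane"),
                          smooth_length = NULL, lambda = 0.6,
                          prune_frac = 0.25) {
  method <- match.arg(method)
  if (lambda <= 0 || lambda > 1) stop("'lambda' must be in (0, 1]",
                                      call. = FALSE)
  if (prune_frac < 0 || prune_frac >= 1)
    stop("'prune_frac' must be in [0, 1)", call. = FALSE)
  structure(list(level = level, method = method,
                 smooth_length = smooth_length, lambda = lambda,
                 prune_frac = prune_frac), class = "detect_config")
}

#' Gyral altitude field
#'
#' The midsurface is the reference separating gyri from sulci; it is
#' realized as a strongly Laplacian-smoothed copy of the surface, and the
#' altitude of a vertex is its signed displacement from the midsurface
#' along the surface normal, translated so that the mean altitude over all
#' vertices is zero.  Positive on gyral crests, negative in sulcal valleys.
#'
#' @param surface A \code{\link{surface_mesh}}.
#' @param config A \code{\link{detect_config}}.
#' @return Numeric vector of class \code{altitude_field} (mm, zero mean).
#' @export
compute_altitude <- function(surface, config = detect_config()) {
  stopifnot(inherits(surface, "surface_mesh"))
  V <- surface$vertices
  if (config$method == "plane") {
    alt <- V[, 3] - mean(V[, 3])
  } else {
    A <- .surface_adjacency(surface)
    deg <- Matrix::rowSums(A)
    deg[deg == 0] <- 1
    e <- .surface_edges(surface)
    h <- mean(sqrt(rowSums((V[e[, 1], , drop = FALSE] -
                              V[e[, 2], , drop = FALSE])^2)))
    Ls <- if (is.null(config$smooth_length)) {
      ## intrinsic default: rigid-motion invariant, scales with the surface
      f <- surface$faces
      a <- V[f[, 2], , drop = FALSE] - V[f[, 1], , drop = FALSE]
      b <- V[f[, 3], , drop = FALSE] - V[f[, 1], , drop = FALSE]
      area <- sum(sqrt(pmax(0, rowSums(a * a) * rowSums(b * b) -
                              rowSums(a * b)^2))) / 2
      sqrt(area) / 8
    } else config$smooth_length
    lam <- config$lambda
    iters <- max(10L, ceiling((2 * Ls / h)^2 / lam))
    ## pin the open boundary: without this, strong smoothing shrinks the
    ## rim of an open sheet inward and the drift leaks into the altitude
    ## through tilted normals
    ek <- .edge_keys(surface$faces)
    open_edges <- names(which(table(ek) == 1L))
    bnd <- unique(as.integer(unlist(strsplit(open_edges, "_", fixed = TRUE))))
    interior <- setdiff(seq_len(nrow(V)), bnd)
    Vs <- V
    for (i in seq_len(iters)) {
      Vn <- (1 - lam) * Vs + lam * as.matrix(A %*% Vs) / deg
      Vs[interior, ] <- Vn[interior, ]
    }
    n <- vertex_normals(surface)
    alt <- rowSums((V - Vs) * n)
    alt <- alt - mean(alt)
  }
  structure(alt, class = "altitude_field")
}

# neighbour lists of every vertex
.adjacency_list <- function(surface) {
  e <- .surface_edges(surface)
  V <- nrow(surface$vertices)
  adj <- split(c(e[, 2], e[, 1]), factor(c(e[, 1], e[, 2]),
                                         levels = seq_len(V)))
  unname(adj)
}

#' Watershed segmentation of gyral crests
#'
#' Grows crest regions by a descending-altitude watershed: vertices are
#' visited from the highest altitude down to the cut level; a vertex joins
#' the basin of its highest already-labelled neighbour, or founds a new
#' basin when it is a local maximum.  Every masked vertex has altitude at
#' or above the level.
#'
#' @param altitude An \code{\link{compute_altitude}} field.
#' @param surface The matching \code{\link{surface_mesh}}.
#' @param level Altitude cut (mm).
#' @return Logical per-vertex crest mask with attributes \code{basin}
#'   (integer basin labels, 0 off-crest) and \code{level}.
#' @export
segment_crests <- function(altitude, surface, level = 0) {
  stopifnot(length(altitude) == nrow(surface$vertices))
  alt <- as.numeric(altitude)
  mask <- alt >= level
  basin <- integer(length(alt))
  if (any(mask)) {
    adj <- .adjacency_list(surface)
    ord <- order(-alt[mask])
    verts <- which(mask)[ord]
    nb <- 0L
    for (v in verts) {
      labs <- basin[adj[[v]]]
      labs <- labs[labs > 0L]
      if (length(labs) == 0L) {
        nb <- nb + 1L
        basin[v] <- nb           # local maximum founds a basin
      } else {
        nbr <- adj[[v]][basin[adj[[v]]] > 0L]
        basin[v] <- basin[nbr[which.max(alt[nbr])]]
      }
    }
  }
  structure(mask, basin = basin, level = level, class = "crest_mask")
}

# walk from a leaf to the nearest junction (or other leaf); returns vertex
# path (leaf first, junction last) and its length
.leaf_branch <- function(leaf, adj, deg, w_of) {
  path <- leaf
  len <- 0
  prev <- 0L
  v <- leaf
  repeat {
    nxt <- setdiff(adj[[v]], prev)
    if (length(nxt) == 0L) break
    nxt <- nxt[1]
    len <- len + w_of(v, nxt)
    path <- c(path, nxt)
    if (deg[nxt] != 2L) break
    prev <- v
    v <- nxt
  }
  list(path = path, len = len)
}

#' Skeletonize segmented gyral crests
#'
#' Three stages per crest component: (i) a distance transform on the mesh
#' (geodesic distance from the crest boundary) highlights the central
#' region; (ii) tree marching connects crest vertices in decreasing
#' centrality into one tree per component; (iii) redundant short leaf
#' branches are pruned, leaving the major branches as the gyral skeleton.
#'
#' @param mask A \code{\link{segment_crests}} mask.
#' @param surface The matching \code{\link{surface_mesh}}.
#' @param altitude The matching altitude field (tie-breaks and fallbacks).
#' @param prune_frac Pruning fraction (see \code{\link{detect_config}}).
#' @return An object of class \code{gyral_net}: the skeleton forest (edge
#'   list on surface vertex ids), per-vertex centrality, component ids and
#'   per-component pruning lengths, plus the crest mask.
#' @export
skeletonize <- function(mask, surface, altitude, prune_frac = 0.25) {
  V <- surface$vertices
  alt <- as.numeric(altitude)
  mvert <- which(as.logical(mask))
  empty <- function() structure(
    list(edges = matrix(numeric(0), 0, 3,
                        dimnames = list(NULL, c("a", "b", "w"))),
         vertices = integer(0), centrality = numeric(0),
         component = integer(0), prune_length = numeric(0),
         crest_mask = mask, surface = surface), class = "gyral_net")
  if (length(mvert) == 0L) return(empty())

  adj_all <- .adjacency_list(surface)
  inmask <- logical(nrow(V)); inmask[mvert] <- TRUE
  ## restricted adjacency + edge weights inside the mask
  adj <- lapply(adj_all, function(nb) nb[inmask[nb]])
  elen <- function(a, b) sqrt(sum((V[a, ] - V[b, ])^2))

  ## --- distance transform: geodesic distance to the crest boundary
  boundary <- mvert[vapply(mvert, function(v)
    any(!inmask[adj_all[[v]]]), TRUE)]
  dist <- rep(NA_real_, nrow(V))
  if (length(boundary)) {
    ## multi-source Dijkstra via a virtual source tied to every boundary
    ## vertex with weight 0
    eM <- .surface_edges(surface)
    eM <- eM[inmask[eM[, 1]] & inmask[eM[, 2]], , drop = FALSE]
    w <- sqrt(rowSums((V[eM[, 1], , drop = FALSE] -
                         V[eM[, 2], , drop = FALSE])^2))
    map <- integer(nrow(V)); map[mvert] <- seq_along(mvert)
    src <- length(mvert) + 1L
    eall <- rbind(cbind(map[eM[, 1]], map[eM[, 2]]),
                  cbind(src, map[boundary]))
    g <- igraph::make_graph(t(eall), n = src, directed = FALSE)
    dd <- igraph::distances(g, v = src,
                            weights = c(w, rep(0, length(boundary))))
    dist[mvert] <- dd[1, map[mvert]]
  } else {
    dist[mvert] <- alt[mvert] - min(alt[mvert])  # no boundary: use altitude
  }
  ## snap to 1e-6 mm so near-ties resolve identically under rigid motions
  ## (round-off in rotated edge lengths must not reorder the marching)
  dist <- round(dist, 6)

  ## --- tree marching: decreasing centrality, attach to the best visited
  ## neighbour (ties broken by vertex id).  A vertex touching several
  ## already-grown trees of the same crest component bridges them -- that
  ## is where skeleton joints are born -- so we keep a union-find over the
  ## growing forest and join every distinct tree met.
  ord <- mvert[order(-dist[mvert], -round(alt[mvert], 9), mvert)]
  visited <- logical(nrow(V))
  parent <- seq_len(nrow(V))
  findp <- function(x) {
    r <- x
    while (parent[r] != r) r <- parent[r]
    while (parent[x] != r) { nxt <- parent[x]; parent[x] <<- r; x <- nxt }
    r
  }
  ea <- integer(0); eb <- integer(0); ew <- numeric(0)
  for (v in ord) {
    nb <- adj[[v]]
    nb <- nb[visited[nb]]
    if (length(nb)) {
      roots <- vapply(nb, findp, 1L)
      for (r in unique(roots)) {
        grp <- nb[roots == r]
        best <- grp[order(-dist[grp], grp)][1]
        ea <- c(ea, best); eb <- c(eb, v); ew <- c(ew, elen(best, v))
        parent[r] <- findp(v)
      }
    }
    visited[v] <- TRUE
  }
  comp <- integer(nrow(V))
  comp[mvert] <- vapply(mvert, findp, 1L)

  ## --- prune short leaf branches, per component
  keep <- rep(TRUE, length(ea))
  alive <- logical(nrow(V)); alive[mvert] <- TRUE
  adj_t <- vector("list", nrow(V))
  for (k in seq_along(ea)) {
    adj_t[[ea[k]]] <- c(adj_t[[ea[k]]], eb[k])
    adj_t[[eb[k]]] <- c(adj_t[[eb[k]]], ea[k])
  }
  wkey <- new.env(hash = TRUE)
  for (k in seq_along(ea))
    assign(paste(min(ea[k], eb[k]), max(ea[k], eb[k])), ew[k], envir = wkey)
  w_of <- function(a, b) get(paste(min(a, b), max(a, b)), envir = wkey)
  deg <- lengths(adj_t)
  prune_len <- numeric(0)
  comps <- sort(unique(comp[mvert]))
  for (cc in comps) {
    repeat {
      cv <- mvert[comp[mvert] == cc & alive[mvert]]
      leaves <- cv[deg[cv] == 1L]
      if (length(leaves) <= 1L) { prune_len[as.character(cc)] <- 0; break }
      br <- lapply(leaves, .leaf_branch, adj = adj_t, deg = deg, w_of = w_of)
      lens <- vapply(br, `[[`, 0, "len")
      lmax <- max(lens)
      ## discretization floor: a twig of one or two mesh edges is always
      ## redundant, whatever the component's branch lengths are
      thr <- max(prune_frac * lmax, 2 * mean(ew))
      prune_len[as.character(cc)] <- thr
      ## only prune twigs that terminate at a junction: a leaf-to-leaf path
      ## is the component's main branch and must survive.  A branch is
      ## judged by its extension beyond the junction's medial blob,
      ## len - dist(junction): corner branches of band caps and lateral
      ## band-width twigs have small extension, while a real gyral spoke
      ## runs on past the junction region (medial-axis style pruning).
      term <- vapply(br, function(x) x$path[length(x$path)], 0L)
      term_deg <- deg[term]
      ext <- lens - dist[term]
      ## a genuine spoke extends past the junction blob by more than the
      ## blob radius itself (corner forks of band caps never do)
      short <- which(ext < pmax(thr, dist[term]) & term_deg >= 3L)
      if (length(short) == 0L) break
      ## remove the shortest offending branch, then re-evaluate
      s <- short[which.min(lens[short])]
      path <- br[[s]]$path
      drop <- path[-length(path)]          # keep the junction endpoint
      for (d in drop) {
        alive[d] <- FALSE
        for (u in adj_t[[d]]) {
          adj_t[[u]] <- setdiff(adj_t[[u]], d)
          deg[u] <- length(adj_t[[u]])
        }
        adj_t[[d]] <- integer(0)
        deg[d] <- 0L
      }
    }
  }
  kept <- alive[ea] & alive[eb]
  ea <- ea[kept]; eb <- eb[kept]; ew <- ew[kept]
  verts <- mvert[alive[mvert]]
  structure(list(
    edges = cbind(a = ea, b = eb, w = ew),
    vertices = verts,
    centrality = dist[verts],
    component = comp[verts],
    prune_length = prune_len,
    crest_mask = mask, surface = surface), class = "gyral_net")
}

#' @export
print.gyral_net <- function(x, ...) {
  deg <- .net_degrees(x)
  cat(sprintf(
    "Gyral net: %d skeleton vertices, %d edges, %d components, %d joints\n",
    length(x$vertices), nrow(x$edges),
    length(unique(x$component)), sum(deg >= 3)))
  invisible(x)
}

# skeleton degree per skeleton vertex (aligned with net$vertices)
.net_degrees <- function(net) {
  tab <- table(factor(c(net$edges[, "a"], net$edges[, "b"]),
                      levels = net$vertices))
  as.integer(tab)
}

.net_adjacency <- function(net) {
  adj <- new.env(hash = TRUE)
  for (k in seq_len(nrow(net$edges))) {
    a <- net$edges[k, "a"]; b <- net$edges[k, "b"]
    assign(as.character(a), c(mget(as.character(a), envir = adj,
                                   ifnotfound = list(integer(0)))[[1]], b),
           envir = adj)
    assign(as.character(b), c(mget(as.character(b), envir = adj,
                                   ifnotfound = list(integer(0)))[[1]], a),
           envir = adj)
  }
  adj
}

#' Find 3-hinge patterns in a gyral net
#'
#' Skeleton vertices with degree greater than 2 are gyral joints; joints
#' closer (along the skeleton) than one pruning-length are merged into a
#' single joint to suppress discretization doubles.  Joints with exactly 3
#' outgoing skeleton branches are 3-hinge patterns: each record carries the
#' center vertex, the three spoke paths traced to the next joint or leaf,
#' and the spoke directions at the center.  Higher-degree joints (4+) are
#' reported separately in the \code{higher_joints} attribute, not counted.
#'
#' @param net A \code{\link{skeletonize}} gyral net.
#' @return List of \code{three_hinge} records with attribute
#'   \code{higher_joints} (data frame of degree-4+ joints).
#' @export
find_3hinges <- function(net) {
  stopifnot(inherits(net, "gyral_net"))
  res <- list()
  higher <- data.frame(vertex = integer(0), degree = integer(0))
  if (length(net$vertices) == 0L || nrow(net$edges) == 0L) {
    attr(res, "higher_joints") <- higher
    return(res)
  }
  V <- net$surface$vertices
  deg <- .net_degrees(net)
  names(deg) <- as.character(net$vertices)
  adj <- .net_adjacency(net)
  nbrs <- function(v) mget(as.character(v), envir = adj,
                           ifnotfound = list(integer(0)))[[1]]
  cent <- stats::setNames(net$centrality, as.character(net$vertices))
  compv <- stats::setNames(net$component, as.character(net$vertices))
  joints <- net$vertices[deg >= 3L]
  if (length(joints) == 0L) {
    attr(res, "higher_joints") <- higher
    return(res)
  }

  ## cluster joints lying within one pruning-length along the skeleton
  cluster <- stats::setNames(seq_along(joints), as.character(joints))
  if (length(joints) > 1L) {
    for (j in joints) {
      lp <- net$prune_length[as.character(compv[as.character(j)])]
      if (is.na(lp) || lp <= 0) next
      ## bounded Dijkstra from j along the skeleton
      dd <- stats::setNames(0, as.character(j))
      queue <- j
      while (length(queue)) {
        v <- queue[which.min(dd[as.character(queue)])]
        queue <- setdiff(queue, v)
        for (u in nbrs(v)) {
          w <- sqrt(sum((V[v, ] - V[u, ])^2))
          cand <- dd[as.character(v)] + w
          if (cand <= lp &&
              (is.na(dd[as.character(u)]) ||
                 cand < dd[as.character(u)] - 1e-12)) {
            dd[as.character(u)] <- cand
            queue <- union(queue, u)
          }
        }
      }
      reached <- intersect(as.integer(names(dd)), joints)
      tgt <- min(cluster[as.character(reached)])
      cluster[as.character(reached)] <- tgt
    }
  }

  for (cl in unique(cluster)) {
    members <- joints[cluster == cl]
    inside <- as.character(members)
    ## outgoing branches: skeleton edges from the cluster to the outside
    out_edges <- list()
    for (m in members) for (u in nbrs(m))
      if (!(as.character(u) %in% inside))
        out_edges[[length(out_edges) + 1L]] <- c(m, u)
    degree_eff <- length(out_edges)
    center <- members[order(-round(cent[as.character(members)], 6),
                            members)][1]
    if (degree_eff == 3L) {
      spokes <- lapply(out_edges, function(ed) {
        path <- c(ed[1], ed[2])
        prev <- ed[1]; v <- ed[2]
        while (length(nbrs(v)) == 2L && !(v %in% joints)) {
          nxt <- setdiff(nbrs(v), prev)
          if (length(nxt) == 0L) break
          path <- c(path, nxt[1])
          prev <- v; v <- nxt[1]
        }
        path
      })
      dirs <- t(vapply(spokes, function(p) {
        tip <- p[min(length(p), 4L)]
        d <- V[tip, ] - V[center, ]
        d / max(sqrt(sum(d^2)), 1e-12)
      }, numeric(3)))
      res[[length(res) + 1L]] <- structure(
        list(center = center, center_xyz = V[center, ],
             spokes = spokes,
             spoke_lengths = vapply(spokes, function(p)
               sum(sqrt(rowSums((V[p[-1], , drop = FALSE] -
                                   V[p[-length(p)], , drop = FALSE])^2))), 0),
             directions = dirs),
        class = "three_hinge")
    } else if (degree_eff >= 4L) {
      higher <- rbind(higher,
                      data.frame(vertex = center, degree = degree_eff))
    }
  }
  attr(res, "higher_joints") <- higher
  res
}

#' @export
print.three_hinge <- function(x, ...) {
  cat(sprintf("3-hinge at (%.2f, %.2f, %.2f), spoke lengths %s mm\n",
              x$center_xyz[1], x$center_xyz[2], x$center_xyz[3],
              paste(sprintf("%.1f", x$spoke_lengths), collapse = "/")))
  invisible(x)
}

#' Detect 3-hinge patterns on a surface
#'
#' Full pipeline: altitude field, watershed crest segmentation,
#' skeletonization and degree-3 joint extraction.  Deterministic for a
#' fixed surface and configuration.
#'
#' @param surface A \code{\link{surface_mesh}}.
#' @param config A \code{\link{detect_config}}.
#' @return An object of class \code{hinge_report}: the gyral net, the list
#'   of \code{three_hinge} records, the count, the degree-4+ joint table
#'   and the altitude field.
#' @export
detect_hinges <- function(surface, config = detect_config()) {
  altitude <- compute_altitude(surface, config)
  mask <- segment_crests(altitude, surface, level = config$level)
  net <- skeletonize(mask, surface, altitude,
                     prune_frac = config$prune_frac)
  hinges <- find_3hinges(net)
  structure(list(net = net, hinges = hinges, count = length(hinges),
                 higher_joints = attr(hinges, "higher_joints"),
                 altitude = altitude, config = config),
            class = "hinge_report")
}

#' @export
print.hinge_report <- function(x, ...) {
  cat(sprintf("Hinge report: %d three-hinge patterns, %d higher joints\n",
              x$count, nrow(x$higher_joints)))
  invisible(x)
}

#' Hinge centers of a report as a matrix
#'
#' @param report A \code{\link{detect_hinges}} report.
#' @return Matrix (count x 3) of hinge center coordinates (mm).
#' @export
hinge_centers <- function(report) {
  if (report$count == 0L) return(matrix(numeric(0), 0, 3))
  t(vapply(report$hinges, function(h) h$center_xyz, numeric(3)))
}

#' Write a per-surface hinge summary as JSON
#'
#' @param report A \code{\link{detect_hinges}} report.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_hinge_report <- function(report, path) {
  centers <- hinge_centers(report)
  obj <- list(count = report$count,
              centers = if (nrow(centers)) unname(apply(centers, 1, as.list))
              else list(),
              spoke_lengths = lapply(report$hinges, function(h)
                as.numeric(h$spoke_lengths)),
              higher_joints = report$higher_joints)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
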