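#' Random maximal planar network by triangle-face node insertion
#'
#' Grows a random triangulation of the sphere: starting from a triangle
#' (whose two faces are both available), each new node is inserted into a
#' uniformly chosen triangular face and connected to its three corners
#' (a T2 move).  Every insertion adds 3 edges and replaces one face with
#' three, so the result has exactly `3 * (n - 2)` edges and `2n - 4` faces,
#' and is planar by construction.  The ensemble has a heavy-tailed degree
#' distribution and small diameters, matching the topology of planar
#' filtered co-expression networks.
#'
#' @param n_nodes number of nodes, `>= 3`.
#' @param seed integer seed; same seed, same network.
#' @param face_selection `"uniform"` (default) picks faces uniformly;
#'   `"degree"` weights faces by the summed degree of their corners, which
#'   skews the tail further.
#' @return an `igraph` with `n_nodes` vertices; graph attribute `n_faces`
#'   records the final face count.
#' @export
t2_random_planar <- function(n_nodes, seed = NULL,
                             face_selection = c("uniform", "degree")) {
  face_selection <- match.arg(face_selection)
  stopifnot(n_nodes >= 3)
  n <- as.integer(n_nodes)
  with_seed(seed, {
    n_faces_final <- 2L * n - 4L
    faces <- matrix(0L, nrow = max(n_faces_final, 2L), ncol = 3L)
    faces[1L, ] <- c(1L, 2L, 3L)
    faces[2L, ] <- c(1L, 2L, 3L)  # inner and outer face of the triangle
    nf <- 2L
    eu <- integer(3L * (n - 2L)); ev <- integer(3L * (n - 2L))
    eu[1:3] <- c(1L, 1L, 2L); ev[1:3] <- c(2L, 3L, 3L)
    ne <- 3L
    deg <- integer(n); deg[1:3] <- 2L
    if (n > 3L) for (v in 4L:n) {
      fi <- if (face_selection == "uniform") sample.int(nf, 1L) else {
        w <- deg[faces[1:nf, 1L]] + deg[faces[1:nf, 2L]] + deg[faces[1:nf, 3L]]
        sample.int(nf, 1L, prob = w)
      }
      f <- faces[fi, ]
      eu[ne + 1:3] <- v; ev[ne + 1:3] <- f
      ne <- ne + 3L
      deg[v] <- 3L; deg[f] <- deg[f] + 1L
      faces[fi, ] <- c(f[1L], f[2L], v)
      faces[nf + 1L, ] <- c(f[1L], f[3L], v)
      faces[nf + 2L, ] <- c(f[2L], f[3L], v)
      nf <- nf + 2L
    }
    g <- igraph::graph_from_edgelist(cbind(eu[1:ne], ev[1:ne]), directed = FALSE)
    g$n_faces <- nf
    g
  })
}

#' Shuffle edge weights of a network
#'
#' Permutes the `weight` edge attribute uniformly at random while leaving
#' the topology untouched; the weight multiset is preserved exactly.
#'
#' @param network weighted `igraph`.
#' @param seed integer seed.
#' @return the network with permuted weights.
#' @export
shuffle_weights <- function(network, seed = NULL) {
  w <- igraph::E(network)$weight
  if (is.null(w)) stop("`network` has no `weight` edge attribute")
  with_seed(seed, {
    igraph::E(network)$weight <- if (length(w) > 1L) sample(w) else w
    network
  })
}

#' Sample a connected node subset by snowball growth
#'
#' Starts at a uniformly chosen node and repeatedly adds a uniformly chosen
#' neighbour of the current set, so the induced subgraph of the returned
#' node set is always connected.  Used to draw size-matched null clusters
#' from random planar parents.
#'
#' @param network connected-enough `igraph` (the component of the start node
#'   must contain at least `size` nodes; resampling is attempted otherwise).
#' @param size number of nodes to sample.
#' @param seed integer seed.
#' @return integer vector of vertex indices.
#' @export
sample_connected_subset <- function(network, size, seed = NULL) {
  n <- igraph::vcount(network)
  stopifnot(size >= 1, size <= n)
  adj <- igraph::as_adj_list(network)
  with_seed(seed, {
    for (attempt in 1:25) {
      sel <- logical(n)
      start <- sample.int(n, 1L)
      sel[start] <- TRUE
      frontier <- as.integer(adj[[start]])
      count <- 1L
      while (count < size && length(frontier) > 0L) {
        v <- frontier[sample.int(length(frontier), 1L)]
        if (!sel[v]) {
          sel[v] <- TRUE
          count <- count + 1L
          frontier <- c(frontier, as.integer(adj[[v]]))
        }
        frontier <- frontier[!sel[frontier]]
      }
      if (count == size) return(which(sel))
    }
    stop("could not sample a connected subset of size ", size)
  })
}
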