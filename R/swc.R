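#' Neuron arbor objects and SWC input/output
#'
#' An SWC file stores a neuron skeleton as one node per line with seven
#' columns: `id`, structure `type` (1 = soma), `x`, `y`, `z` (micrometres),
#' `radius` (micrometres) and `parent` id (`-1` for the root). A
#' `neuron_arbor` is the validated in-memory form: a rooted, connected,
#' acyclic tree with a single root.
#'
#' @param nodes data frame with columns `id`, `type`, `x`, `y`, `z`,
#'   `radius`, `parent`.
#' @return `neuron_arbor()` returns a validated object of class
#'   `"neuron_arbor"`: the node table plus a `root` attribute (row index of
#'   the root node).
#' @examples
#' y <- neuron_arbor(data.frame(
#'   id = 1:4, type = c(1, 3, 3, 3),
#'   x = c(0, 5, 9, 9), y = c(0, 0, 3, -3), z = 0,
#'   radius = 1, parent = c(-1, 1, 2, 2)))
#' total_cable_length(y)
#' @export
neuron_arbor <- function(nodes) {
  req <- c("id", "type", "x", "y", "z", "radius", "parent")
  if (!is.data.frame(nodes) || !all(req %in% names(nodes)))
    stop("`nodes` must be a data frame with columns ",
         paste(req, collapse = ", "), call. = FALSE)
  nodes <- as.data.frame(nodes)[req]
  n <- nrow(nodes)
  if (n < 1L) stop("arbor must contain at least one node", call. = FALSE)
  if (anyDuplicated(nodes$id))
    stop("duplicate node ids in arbor", call. = FALSE)
  if (!all(is.finite(as.matrix(nodes[c("x", "y", "z")]))))
    stop("non-finite coordinates in arbor", call. = FALSE)
  root <- which(nodes$parent == -1)
  if (length(root) != 1L)
    stop("arbor must have exactly one root (parent -1), found ",
         length(root), call. = FALSE)
  pidx <- match(nodes$parent, nodes$id)
  bad <- which(is.na(pidx) & nodes$parent != -1)
  if (length(bad))
    stop(sprintf("node id %s (line %d) references absent parent %s",
                 nodes$id[bad[1]], bad[1], nodes$parent[bad[1]]), call. = FALSE)
  # connectivity/acyclicity: every node must reach the root
  depth <- rep.int(NA_integer_, n)
  depth[root] <- 0L
  for (i in seq_len(n)) {
    if (!is.na(depth[i])) next
    chain <- i
    j <- i
    while (is.na(depth[j])) {
      j <- pidx[j]
      if (j %in% chain)
        stop("cycle detected in arbor involving node id ", nodes$id[j],
             call. = FALSE)
      chain <- c(chain, j)
    }
    base <- depth[j]
    depth[rev(chain[-length(chain)])] <- base + seq_len(length(chain) - 1L)
  }
  structure(nodes, root = root, class = c("neuron_arbor", "data.frame"))
}

#' @rdname neuron_arbor
#' @param file path or connection to a 7-column SWC file; lines starting
#'   with `#` are comments.
#' @export
read_swc <- function(file) {
  lines <- readLines(file)
  keep <- !grepl("^\\s*(#|$)", lines)
  ln <- which(keep)
  if (!length(ln)) stop("no data lines in SWC file", call. = FALSE)
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  nf <- lengths(fields)
  if (any(nf != 7L))
    stop("line ", ln[which(nf != 7L)[1]], ": expected 7 SWC columns, found ",
         nf[nf != 7L][1], call. = FALSE)
  m <- matrix(as.numeric(unlist(fields)), ncol = 7L, byrow = TRUE)
  if (anyNA(m)) {
    bad <- which(apply(is.na(m), 1L, any))[1]
    stop("line ", ln[bad], ": non-numeric SWC field", call. = FALSE)
  }
  nodes <- data.frame(id = m[, 1], type = m[, 2], x = m[, 3], y = m[, 4],
                      z = m[, 5], radius = m[, 6], parent = m[, 7])
  tryCatch(neuron_arbor(nodes), error = function(e)
    stop("invalid SWC ", if (is.character(file)) file else "stream", ": ",
         conditionMessage(e), call. = FALSE))
}

#' @rdname neuron_arbor
#' @param arbor a `neuron_arbor`.
#' @export
write_swc <- function(arbor, file) {
  stopifnot(inherits(arbor, "neuron_arbor"))
  hdr <- "# SWC: id type x y z radius parent"
  body <- sprintf("%d %d %.17g %.17g %.17g %.17g %d",
                  as.integer(arbor$id), as.integer(arbor$type),
                  arbor$x, arbor$y, arbor$z, arbor$radius,
                  as.integer(arbor$parent))
  writeLines(c(hdr, body), file)
  invisible(file)
}

#' @export
print.neuron_arbor <- function(x, ...) {
  cat(sprintf("<neuron_arbor> %d nodes, %d tips, total length %.2f um\n",
              nrow(x), sum(!x$id %in% x$parent),
              total_cable_length(x)))
  invisible(x)
}

# Row index of each node's parent (NA for root).
parent_index <- function(arbor) {
  pidx <- match(arbor$parent, arbor$id)
  pidx[attr(arbor, "root")] <- NA_integer_
  pidx
}

# Length of the edge from each node to its parent (0 for root).
edge_lengths <- function(arbor) {
  pidx <- parent_index(arbor)
  xyz <- as.matrix(arbor[c("x", "y", "z")])
  d <- xyz - xyz[ifelse(is.na(pidx), seq_len(nrow(xyz)), pidx), , drop = FALSE]
  len <- sqrt(rowSums(d^2))
  len[is.na(pidx)] <- 0
  len
}

#' Total cable length of an arbor
#'
#' Sum of Euclidean edge lengths over the skeleton, in micrometres.
#'
#' @param arbor a `neuron_arbor`.
#' @export
total_cable_length <- function(arbor) sum(edge_lengths(arbor))
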