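#' Cell-by-gene count matrices with condition metadata
#'
#' Container for an immune-cell count matrix: non-negative integer counts
#' (cells x genes, sparse), a rearing condition per cell (`CVZ` =
#' conventionalized, `GF` = germ-free), and optionally the true generating
#' cell type (synthetic data only).
#'
#' @param counts cells x genes matrix of non-negative integers (dense or
#'   `Matrix` sparse); gene names as column names, cell ids as row names.
#' @param condition character/factor per cell, values `"CVZ"` or `"GF"`.
#' @param true_type optional per-cell generating type.
#' @return Object of class `"expression_matrix"` with elements `counts`
#'   (a `dgCMatrix`), `cells` (metadata data frame) and `genes`.
#' @export
expression_matrix <- function(counts, condition, true_type = NULL) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  if (any(counts@x < 0) || any(counts@x != round(counts@x)))
    stop("counts must be non-negative integers", call. = FALSE)
  n <- nrow(counts)
  condition <- as.character(condition)
  if (length(condition) != n)
    stop("`condition` must have one value per cell", call. = FALSE)
  if (!all(condition %in% c("CVZ", "GF")))
    stop('`condition` values must be "CVZ" or "GF"', call. = FALSE)
  if (is.null(rownames(counts))) rownames(counts) <- paste0("cell", seq_len(n))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("g", seq_len(ncol(counts)))
  cells <- data.frame(cell_id = rownames(counts), condition = condition,
                      stringsAsFactors = FALSE)
  if (!is.null(true_type)) {
    stopifnot(length(true_type) == n)
    cells$true_type <- as.character(true_type)
  }
  structure(list(counts = counts, cells = cells, genes = colnames(counts)),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d cells x %d genes (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s: %d", names(table(x$cells$condition)),
                            table(x$cells$condition)), collapse = ", ")))
  invisible(x)
}

#' Write and read an expression matrix (MatrixMarket + TSV)
#'
#' On disk the counts are a genes x cells MatrixMarket `.mtx` (the common
#' single-cell convention) with `genes.tsv` (one symbol per line) and
#' `cells.tsv` (`cell_id`, `condition`, optional `true_type`).
#'
#' @param expr an [expression_matrix()].
#' @param dir directory for `counts.mtx`, `genes.tsv`, `cells.tsv`.
#' @export
write_expression <- function(expr, dir) {
  stopifnot(inherits(expr, "expression_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::t(expr$counts), file.path(dir, "counts.mtx"))
  writeLines(expr$genes, file.path(dir, "genes.tsv"))
  utils::write.table(expr$cells, file.path(dir, "cells.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname write_expression
#' @export
read_expression <- function(dir) {
  m <- Matrix::t(Matrix::readMM(file.path(dir, "counts.mtx")))
  genes <- readLines(file.path(dir, "genes.tsv"))
  cells <- utils::read.delim(file.path(dir, "cells.tsv"),
                             stringsAsFactors = FALSE)
  dimnames(m) <- list(cells$cell_id, genes)
  expression_matrix(m, cells$condition,
                    true_type = cells$true_type)
}

#' Stand-in 75-gene microglial fingerprint
#'
#' The real fingerprint is a curated list of genes whose combinatorial
#' expression distinguishes microglia from macrophages across species.
#' The synthetic generator plants a stand-in list of 75 symbols: a few
#' well-known microglial genes (c1qa, c1qb, apoeb, hexb, mafb, p2ry12,
#' csf1ra, slc7a7) plus numbered placeholders.
#'
#' @return Character vector of 75 gene symbols.
#' @export
fingerprint_genes <- function() {
  known <- c("c1qa", "c1qb", "apoeb", "hexb", "mafb", "p2ry12", "csf1ra",
             "slc7a7")
  c(known, sprintf("mgl%02d", seq_len(75 - length(known))))
}

#' Parameters for the synthetic immune-cell count generator
#'
#' Generates negative-binomial counts for a mixture of immune cell types
#' resembling a reclustered mpeg1+ population: ramified, amoeboid and
#' proliferative microglia plus macrophages. All microglial types express
#' the 75-gene fingerprint at `fingerprint_high_mean`; macrophages express
#' only a small subset (10 genes) of it. Each type additionally gets its
#' own marker-gene block so types are separable, and `condition_lfc`
#' plants log2 fold changes between conditions (CVZ vs GF) in chosen cell
#' types — by default the complement genes c1qa/c1qb are higher in CVZ
#' within ramified microglia and higher in GF within amoeboid microglia.
#'
#' @param n_cells_per_type named counts; names are the cell types.
#' @param n_genes total genes (>= 75 fingerprint + markers).
#' @param fingerprint_high_mean mean fingerprint count in microglia.
#' @param background_mean mean count for unexpressed genes.
#' @param marker_mean mean count of a type's own marker block.
#' @param n_markers_per_type marker block size.
#' @param condition_lfc named list: cell type -> named numeric vector of
#'   log2 fold changes (CVZ relative to GF) per gene.
#' @param dispersion negative-binomial overdispersion (var = mu + disp *
#'   mu^2).
#' @param seed integer RNG seed.
#' @return Validated list of class `"expr_params"`.
#' @export
expr_params <- function(n_cells_per_type = c(ramified_microglia = 70,
                                             amoeboid_microglia = 60,
                                             proliferative_microglia = 50,
                                             macrophage1 = 75,
                                             macrophage2 = 72,
                                             macrophage3 = 65),
                        n_genes = 400,
                        fingerprint_high_mean = 20,
                        background_mean = 0.01,
                        marker_mean = 20,
                        n_markers_per_type = 30,
                        condition_lfc = list(
                          ramified_microglia = c(c1qa = 1, c1qb = 1),
                          amoeboid_microglia = c(c1qa = -1, c1qb = -1)),
                        dispersion = 0.5,
                        seed = 1) {
  stopifnot(is.numeric(n_cells_per_type), !is.null(names(n_cells_per_type)),
            all(n_cells_per_type >= 1))
  check_scalar(n_genes, "n_genes", lower = 1)
  check_scalar(fingerprint_high_mean, "fingerprint_high_mean", lower = 0,
               strict_lower = TRUE)
  check_scalar(background_mean, "background_mean", lower = 0)
  check_scalar(marker_mean, "marker_mean", lower = 0)
  check_scalar(n_markers_per_type, "n_markers_per_type", lower = 1)
  check_scalar(dispersion, "dispersion", lower = 0, strict_lower = TRUE)
  check_scalar(seed, "seed")
  need <- 75 + n_markers_per_type * length(n_cells_per_type)
  if (n_genes < need)
    stop(sprintf("n_genes = %d cannot hold 75 fingerprint + %d marker genes",
                 n_genes, need - 75), call. = FALSE)
  if (missing(condition_lfc))  # default effects only for present types
    condition_lfc <- condition_lfc[names(condition_lfc) %in%
                                     names(n_cells_per_type)]
  stopifnot(is.list(condition_lfc),
            all(names(condition_lfc) %in% names(n_cells_per_type)))
  structure(list(n_cells_per_type = n_cells_per_type, n_genes = n_genes,
                 fingerprint_high_mean = fingerprint_high_mean,
                 background_mean = background_mean,
                 marker_mean = marker_mean,
                 n_markers_per_type = n_markers_per_type,
                 condition_lfc = condition_lfc,
                 dispersion = dispersion, seed = seed),
            class = "expr_params")
}

#' Generate a synthetic immune-cell count matrix
#'
#' @param params an [expr_params()] object.
#' @return An [expression_matrix()] with balanced CVZ/GF conditions per
#'   cell type and `true_type` metadata.
#' @export
gen_expression <- function(params) {
  stopifnot(inherits(params, "expr_params"))
  with_seed(params$seed, {
    types <- names(params$n_cells_per_type)
    fp <- fingerprint_genes()
    marker_names <- unlist(lapply(types, function(ty)
      sprintf("%s_mk%02d", ty, seq_len(params$n_markers_per_type))))
    n_null <- params$n_genes - 75 - length(marker_names)
    genes <- c(fp, marker_names,
               if (n_null > 0) sprintf("null%03d", seq_len(n_null)))
    ncells <- sum(params$n_cells_per_type)
    type_of <- rep(types, params$n_cells_per_type)
    # balanced conditions within each type
    condition <- unlist(lapply(params$n_cells_per_type, function(k)
      rep_len(c("CVZ", "GF"), k)))
    mu <- matrix(params$background_mean, ncells, params$n_genes,
                 dimnames = list(NULL, genes))
    micro <- grepl("microglia", types)
    for (i in seq_along(types)) {
      rows <- type_of == types[i]
      if (micro[i]) {
        mu[rows, fp] <- params$fingerprint_high_mean
      } else {
        # macrophages share a small subset of the fingerprint
        mu[rows, fp[seq_len(10)]] <- params$fingerprint_high_mean
      }
      mk <- sprintf("%s_mk%02d", types[i], seq_len(params$n_markers_per_type))
      mu[rows, mk] <- params$marker_mean
    }
    # planted condition effects (lfc = log2 CVZ / GF), split symmetrically
    for (ty in names(params$condition_lfc)) {
      lfc <- params$condition_lfc[[ty]]
      for (g in names(lfc)) {
        if (!g %in% genes) stop("condition_lfc gene not present: ", g,
                                call. = FALSE)
        rows_cvz <- type_of == ty & condition == "CVZ"
        rows_gf <- type_of == ty & condition == "GF"
        mu[rows_cvz, g] <- mu[rows_cvz, g] * 2^(lfc[[g]] / 2)
        mu[rows_gf, g] <- mu[rows_gf, g] * 2^(-lfc[[g]] / 2)
      }
    }
    size <- 1 / params$dispersion
    counts <- matrix(stats::rnbinom(length(mu), mu = as.numeric(mu),
                                    size = size),
                     ncells, params$n_genes, dimnames = list(NULL, genes))
    expression_matrix(counts, condition, true_type = type_of)
  })
}
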