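#' Directed weighted connectome with tract lengths and region metadata
#'
#' Container for a whole-brain structural connectome. The weight matrix
#' `W` is oriented target-row / source-column: entry `W[i, j]` is the
#' strength of the projection from region `j` to region `i`, so that the
#' afferent input of region `i` is the row sum over sources. `L` holds
#' tract lengths in mm on the same index pair. Region labels carry a
#' hemisphere suffix (`"_L"` / `"_R"`); the base label identifies
#' homotopic partners across hemispheres. `groups` is a named registry of
#' region sets (base labels or full labels), e.g. the default-mode,
#' insular and frontal groups.
#'
#' @param W Non-negative square matrix, zero diagonal.
#' @param L Tract-length matrix, mm; finite wherever `W > 0`.
#' @param labels Character region labels, unique, same length as
#'   `nrow(W)`.
#' @param hemisphere `"left"`/`"right"` per region; derived from the label
#'   suffix when omitted.
#' @param groups Named list of character vectors; every member must
#'   resolve to a label or a base label.
#' @return An object of class `"connectome"`.
#' @export
connectome <- function(W, L, labels, hemisphere = NULL, groups = list()) {
  W <- as.matrix(W); L <- as.matrix(L)
  n <- length(labels)
  if (is.null(hemisphere))
    hemisphere <- ifelse(grepl("_L$", labels), "left",
                         ifelse(grepl("_R$", labels), "right",
                                NA_character_))
  conn <- structure(list(n_regions = n, W = unname(W), L = unname(L),
                         labels = as.character(labels),
                         hemisphere = as.character(hemisphere),
                         groups = groups),
                    class = "connectome")
  validate_connectome(conn)
  conn
}

validate_connectome <- function(conn) {
  n <- conn$n_regions
  if (!all(dim(conn$W) == c(n, n)))
    stop(sprintf("weight matrix is %dx%d but there are %d labels",
                 nrow(conn$W), ncol(conn$W), n), call. = FALSE)
  if (!all(dim(conn$L) == dim(conn$W)))
    stop("weight and length matrices must have the same shape",
         call. = FALSE)
  neg <- which(conn$W < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop(sprintf("negative weight at (row %d, col %d): %g", neg[1, 1],
                 neg[1, 2], conn$W[neg[1, 1], neg[1, 2]]), call. = FALSE)
  if (any(diag(conn$W) != 0))
    stop("diagonal of W must be zero (no self-projections)", call. = FALSE)
  bad <- which(conn$W > 0 & !is.finite(conn$L), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-finite tract length at connected pair (row %d, col %d)",
                 bad[1, 1], bad[1, 2]), call. = FALSE)
  if (anyDuplicated(conn$labels))
    stop("region labels must be unique", call. = FALSE)
  if (length(conn$hemisphere) != n)
    stop("one hemisphere entry per region required", call. = FALSE)
  for (g in names(conn$groups)) {
    miss <- setdiff(conn$groups[[g]],
                    c(conn$labels, base_label(conn$labels)))
    if (length(miss) > 0)
      stop(sprintf("group '%s' has unknown member(s): %s", g,
                   paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(conn)
}

base_label <- function(labels) sub("_[LR]$", "", labels)

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("connectome: %d regions (%d left, %d right), %d directed edges\n",
              x$n_regions, sum(x$hemisphere == "left"),
              sum(x$hemisphere == "right"), sum(x$W > 0)))
  if (length(x$groups))
    cat("  groups:", paste(sprintf("%s (%d)", names(x$groups),
                                   lengths(x$groups)), collapse = ", "), "\n")
  invisible(x)
}

#' Resolve region labels, base labels or group names to indices
#'
#' @param conn A [connectome()].
#' @param what Character vector of full labels, base labels (matching both
#'   hemispheres) or group names.
#' @param hemisphere Restrict the result to one hemisphere.
#' @return Sorted integer indices into the region list.
#' @export
resolve_regions <- function(conn, what,
                            hemisphere = c("both", "left", "right")) {
  hemisphere <- match.arg(hemisphere)
  bases <- base_label(conn$labels)
  idx <- integer(0)
  for (x in what) {
    if (x %in% names(conn$groups))
      idx <- c(idx, resolve_regions(conn, conn$groups[[x]]))
    else if (x %in% conn$labels)
      idx <- c(idx, match(x, conn$labels))
    else if (x %in% bases)
      idx <- c(idx, which(bases == x))
    else
      stop(sprintf("unknown region or group: '%s'", x), call. = FALSE)
  }
  idx <- sort(unique(idx))
  if (hemisphere != "both")
    idx <- idx[conn$hemisphere[idx] == hemisphere]
  idx
}

#' Load a connectome from delimited text files
#'
#' The weight and length files are comma-separated matrices whose first
#' column and header row carry the region labels (the header states the
#' orientation in a leading comment line); the labels file is
#' tab-separated with columns `label` and `hemisphere`. Orientation is
#' asserted on load: header labels must match the labels file exactly, in
#' order.
#'
#' @param weights_path,lengths_path CSV matrix files (see
#'   [write_connectome()] for the exact layout).
#' @param labels_path TSV with columns `label`, `hemisphere`.
#' @param groups_path Optional JSON-style file mapping group names to
#'   label vectors (a minimal subset of JSON is parsed; files written by
#'   [write_connectome()] round-trip).
#' @return A validated [connectome()].
#' @export
load_connectome <- function(weights_path, lengths_path, labels_path,
                            groups_path = NULL) {
  labs <- utils::read.delim(labels_path, stringsAsFactors = FALSE)
  if (!all(c("label", "hemisphere") %in% names(labs)))
    stop("labels file needs columns 'label' and 'hemisphere'")
  read_mat <- function(path) {
    m <- utils::read.csv(path, check.names = FALSE, comment.char = "#",
                         row.names = 1)
    if (!identical(rownames(m), labs$label) ||
        !identical(colnames(m), labs$label))
      stop(sprintf("matrix header of '%s' does not match the labels file",
                   path), call. = FALSE)
    as.matrix(m)
  }
  groups <- if (is.null(groups_path)) list() else read_groups_json(groups_path)
  connectome(read_mat(weights_path), read_mat(lengths_path), labs$label,
             labs$hemisphere, groups)
}

#' Write a connectome to delimited text files
#'
#' @param conn A [connectome()].
#' @param dir Output directory; files `weights.csv`, `lengths.csv`,
#'   `labels.tsv` and (when groups exist) `groups.json` are created.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_connectome <- function(conn, dir) {
  stopifnot(inherits(conn, "connectome"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(weights = file.path(dir, "weights.csv"),
             lengths = file.path(dir, "lengths.csv"),
             labels = file.path(dir, "labels.tsv"))
  write_mat <- function(m, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("# orientation: target rows, source columns (W[i,j] = j -> i)",
               con)
    dimnames(m) <- list(conn$labels, conn$labels)
    utils::write.csv(m, con, quote = FALSE)
  }
  write_mat(conn$W, paths["weights"])
  write_mat(conn$L, paths["lengths"])
  utils::write.table(data.frame(label = conn$labels,
                                hemisphere = conn$hemisphere),
                     paths["labels"], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  if (length(conn$groups)) {
    paths <- c(paths, groups = file.path(dir, "groups.json"))
    write_groups_json(conn$groups, paths["groups"])
  }
  invisible(paths)
}

write_groups_json <- function(groups, path) {
  jsonlite::write_json(groups, path, pretty = TRUE)
  invisible(path)
}

read_groups_json <- function(path) {
  lapply(jsonlite::read_json(path), function(g) unlist(g, use.names = FALSE))
}

#' Homotopic partner index of every region
#'
#' @param conn A [connectome()].
#' @return Integer vector: `partner[i]` is the index of the region with
#'   the same base label in the other hemisphere. Errors listing orphans
#'   when a region has no partner.
#' @export
homotopic_partners <- function(conn) {
  bases <- base_label(conn$labels)
  partner <- integer(conn$n_regions)
  for (i in seq_len(conn$n_regions)) {
    j <- which(bases == bases[i] & conn$hemisphere != conn$hemisphere[i])
    partner[i] <- if (length(j) == 1) j else NA_integer_
  }
  if (anyNA(partner))
    stop(sprintf("regions without a homotopic partner: %s",
                 paste(conn$labels[is.na(partner)], collapse = ", ")),
         call. = FALSE)
  partner
}

#' Equalise weights and tract lengths across hemispheres
#'
#' Replaces every ordered-pair entry and its hemisphere-swapped image by
#' their symmetrisation (`method = "mean"` by default), making the
#' connectome invariant under the hemisphere-swap permutation. Applying
#' the operation twice changes nothing.
#'
#' @param conn A [connectome()] in which every region has a homotopic
#'   partner.
#' @param method `"mean"`, `"min"` or `"max"` of the two homotopic
#'   entries.
#' @return The mirrored [connectome()].
#' @export
mirror_hemispheres <- function(conn, method = c("mean", "min", "max")) {
  method <- match.arg(method)
  p <- homotopic_partners(conn)
  f <- switch(method, mean = function(a, b) (a + b) / 2, min = pmin,
              max = pmax)
  sym <- function(M) {
    Ms <- M[p, p]
    out <- f(M, Ms)
    # keep non-finite lengths of unconnected pairs from polluting entries
    out[is.na(out)] <- M[is.na(out)]
    out
  }
  conn$W <- sym(conn$W)
  conn$L <- sym(conn$L)
  validate_connectome(conn)
  conn
}

#' Transmission delays from tract lengths
#'
#' `delay[i, j] = L[i, j] / v_ax`, converted to ms (mm divided by m/s is
#' ms), and forced to zero where no projection exists.
#'
#' @param conn A [connectome()].
#' @param v_ax Axonal propagation speed, m/s.
#' @return Matrix of delays in ms with attribute `v_ax`; class
#'   `"delay_matrix"`.
#' @examples
#' # 3 mm at 3 m/s is 1 ms
#' @export
compute_delays <- function(conn, v_ax = 3) {
  stopifnot(inherits(conn, "connectome"), v_ax > 0)
  D <- conn$L / v_ax
  D[conn$W == 0] <- 0
  D[!is.finite(D)] <- 0
  structure(D, v_ax = v_ax, class = c("delay_matrix", class(D)))
}

#' Global coupling normalisation constant
#'
#' Raw tracer weights are dimensionless; the network model rescales them
#' by a single global constant so that afferent drives sit in a
#' physiological range. The default rule divides by the maximum
#' in-strength (largest row sum of `W`).
#'
#' @param conn A [connectome()].
#' @return Scalar scale factor to multiply `W` by.
#' @export
coupling_scale <- function(conn) {
  s <- max(rowSums(conn$W))
  if (s <= 0) 1 else 1 / s
}
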