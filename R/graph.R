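# Proportional thresholding and hemisphere-resolved community edge counts.

#' Canonical resting-state-network communities
#'
#' The seven canonical cortical networks (frontoparietal FPN, limbic LM,
#' salience SAL, dorsal attention DAN, default mode DMN, somatomotor SMN,
#' visual VN), each split by hemisphere, giving 14 communities. Order is
#' fixed so inter-community pair names are reproducible.
#'
#' @return Character vector of the 14 community names (`FPN_L`, `FPN_R`,
#'   ..., `VN_R`).
#' @export
community_names <- function() {
  nets <- c("FPN", "LM", "SAL", "DAN", "DMN", "SMN", "VN")
  as.vector(t(outer(nets, c("L", "R"), paste, sep = "_")))
}

#' Names of the 91 unordered community pairs
#' @return Character vector `"A:B"` in canonical order.
#' @export
community_pair_names <- function() {
  cn <- community_names()
  idx <- utils::combn(length(cn), 2L)
  paste(cn[idx[1L, ]], cn[idx[2L, ]], sep = ":")
}

#' Proportional thresholding and binarization
#'
#' Retains the `k = floor(density * n(n-1)/2)` largest off-diagonal unique
#' entries of a symmetric connectivity matrix as edges of a binary
#' undirected graph, so graph density is identical across subjects. Ties
#' are broken deterministically by (value descending, row index ascending,
#' column index ascending). `NA` entries are never retained.
#'
#' @param C Symmetric numeric matrix (diagonal ignored).
#' @param density Proportion of the strongest connections to keep, in
#'   `(0, 1]`. Default 0.15.
#' @return Binary symmetric matrix (0/1, zero diagonal) with attributes
#'   `density` and `n_edges`.
#' @export
#' @examples
#' C <- matrix(runif(25), 5); C <- (C + t(C)) / 2; diag(C) <- NA
#' sum(threshold_proportional(C, 0.2)) / 2  # floor(0.2 * 10) = 2 edges
threshold_proportional <- function(C, density = 0.15) {
  if (!is.matrix(C) || nrow(C) != ncol(C)) stop("'C' must be square", call. = FALSE)
  if (!(density > 0 && density <= 1)) {
    stop("'density' must be in (0, 1], got ", density, call. = FALSE)
  }
  n <- nrow(C)
  ut <- which(upper.tri(C), arr.ind = TRUE)
  vals <- C[ut]
  if (all(is.na(vals))) stop("all off-diagonal entries are NA", call. = FALSE)
  k <- floor(density * n * (n - 1) / 2)
  ord <- order(-vals, ut[, 1L], ut[, 2L], na.last = TRUE)
  keep <- ord[seq_len(min(k, sum(!is.na(vals))))]
  A <- matrix(0L, n, n, dimnames = dimnames(C))
  A[ut[keep, , drop = FALSE]] <- 1L
  A <- A + t(A)
  attr(A, "density") <- density
  attr(A, "n_edges") <- length(keep)
  attr(A, "band") <- attr(C, "band")
  A
}

#' Load an ROI-to-community partition table
#'
#' Reads a TSV with columns `roi_label`, `network`, `hemisphere` and maps
#' each ROI label onto one of the 14 hemisphere-resolved communities.
#' Labels present in `labels` but absent from the table are mapped to
#' `"unassigned"` (with a warning), mirroring templates that do not cover
#' sub-cortical regions; their edges are kept and surface downstream in the
#' `unassigned_touching` bucket rather than silently vanishing.
#'
#' @param path Path to the partition TSV.
#' @param labels Character vector of the cohort's ROI labels.
#' @return Named character vector: `labels -> community` (class
#'   `network_partition`).
#' @export
#' @examples
#' # bundled partition for the 60-ROI synthetic geometry
#' f <- system.file("extdata", "synthetic_partition_60.tsv",
#'                  package = "aecnet")
#' p <- load_partition(f, sprintf("roi_%03d", 1:60))
#' table(p)[1:3]
load_partition <- function(path, labels) {
  if (!file.exists(path)) stop("partition file not found: ", path, call. = FALSE)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("roi_label", "network", "hemisphere")
  if (!all(need %in% names(tab))) {
    stop("partition file '", path, "' must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(tab$roi_label)) {
    stop("duplicate roi_label in partition file '", path, "': ",
         paste(unique(tab$roi_label[duplicated(tab$roi_label)]),
               collapse = ", "), call. = FALSE)
  }
  nets <- c("FPN", "LM", "SAL", "DAN", "DMN", "SMN", "VN")
  bad <- setdiff(unique(tab$network), nets)
  if (length(bad)) {
    stop("unknown network name(s) in partition file '", path, "': ",
         paste(bad, collapse = ", "), "; expected one of ",
         paste(nets, collapse = ", "), call. = FALSE)
  }
  if (!all(tab$hemisphere %in% c("L", "R"))) {
    stop("hemisphere must be 'L' or 'R' in partition file '", path, "'",
         call. = FALSE)
  }
  comm <- paste(tab$network, tab$hemisphere, sep = "_")
  names(comm) <- tab$roi_label
  out <- comm[labels]
  missing <- is.na(out)
  if (any(missing)) {
    warning(sum(missing), " ROI label(s) absent from the partition table; ",
            "mapped to 'unassigned'", call. = FALSE)
    out[missing] <- "unassigned"
  }
  names(out) <- labels
  class(out) <- "network_partition"
  out
}

#' Default partition for the synthetic geometry
#'
#' Assigns ROI labels to the 14 communities in contiguous blocks of
#' near-equal size (the first communities in canonical order absorb the
#' remainder). Purely synthetic bookkeeping so downstream modules are
#' exercised with a fully specified 14-community partition.
#'
#' @param labels ROI labels to partition.
#' @return A `network_partition` (named character vector).
#' @export
make_default_partition <- function(labels) {
  n <- length(labels)
  cn <- community_names()
  if (n < length(cn)) {
    # tiny geometries: cycle through the communities (some stay empty-ish)
    out <- rep_len(cn, n)
    names(out) <- labels
    class(out) <- "network_partition"
    return(out)
  }
  base <- n %/% length(cn)
  extra <- n %% length(cn)
  sizes <- rep(base, length(cn)) + c(rep(1L, extra),
                                     rep(0L, length(cn) - extra))
  out <- rep(cn, times = sizes)
  names(out) <- labels
  class(out) <- "network_partition"
  out
}

#' Write a partition as TSV
#' @param partition A `network_partition`.
#' @param path Output path.
#' @export
write_partition <- function(partition, path) {
  assigned <- partition != "unassigned"
  parts <- do.call(rbind, strsplit(unname(partition[assigned]), "_"))
  df <- data.frame(roi_label = names(partition)[assigned],
                   network = parts[, 1L], hemisphere = parts[, 2L],
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Intra- and inter-community edge counts
#'
#' Splits the retained edges of a binarized adjacency matrix by the
#' community membership of their endpoints: 14 intra-community counts, 91
#' inter-community pair counts, and one `unassigned_touching` bucket for
#' edges with at least one unassigned endpoint. The counts always conserve
#' the total: `sum(intra) + sum(inter) + unassigned_touching = n_edges`.
#'
#' @param A Binary symmetric adjacency matrix (from
#'   [threshold_proportional()]); must have ROI labels as dimnames or the
#'   same length as `partition`.
#' @param partition A `network_partition` over the same ROI labels.
#' @return Object of class `community_edge_counts`: list with named
#'   vectors `intra` (14), `inter` (91), scalar `unassigned_touching`,
#'   `total_edges`, plus `band` and `density` carried from `A`.
#' @export
community_edge_counts <- function(A, partition) {
  labels <- rownames(A) %||% names(partition)
  if (length(partition) != nrow(A)) {
    stop("partition covers ", length(partition), " ROIs but adjacency has ",
         nrow(A), call. = FALSE)
  }
  if (!is.null(rownames(A)) &&
      !identical(sort(rownames(A)), sort(names(partition)))) {
    stop("adjacency and partition label sets differ", call. = FALSE)
  }
  memb <- unname(partition[labels])
  cn <- community_names()
  pn <- community_pair_names()
  intra <- stats::setNames(integer(length(cn)), cn)
  inter <- stats::setNames(integer(length(pn)), pn)
  unass <- 0L
  e <- which(upper.tri(A) & A != 0, arr.ind = TRUE)
  if (nrow(e)) {
    ci <- memb[e[, 1L]]
    cj <- memb[e[, 2L]]
    touch_un <- ci == "unassigned" | cj == "unassigned"
    unass <- sum(touch_un)
    same <- !touch_un & ci == cj
    if (any(same)) {
      t1 <- table(ci[same])
      intra[names(t1)] <- intra[names(t1)] + as.integer(t1)
    }
    cross <- !touch_un & !same
    if (any(cross)) {
      o1 <- pmin(match(ci[cross], cn), match(cj[cross], cn))
      o2 <- pmax(match(ci[cross], cn), match(cj[cross], cn))
      key <- paste(cn[o1], cn[o2], sep = ":")
      t2 <- table(key)
      inter[names(t2)] <- inter[names(t2)] + as.integer(t2)
    }
  }
  total <- nrow(e)
  stopifnot(sum(intra) + sum(inter) + unass == total)  # conservation
  structure(list(intra = intra, inter = inter, unassigned_touching = unass,
                 total_edges = total,
                 band = attr(A, "band"), density = attr(A, "density")),
            class = "community_edge_counts")
}

#' @export
print.community_edge_counts <- function(x, ...) {
  cat(sprintf(paste0("<community_edge_counts> %d edges: %d intra, %d inter,",
                     " %d touching unassigned\n"),
              x$total_edges, sum(x$intra), sum(x$inter),
              x$unassigned_touching))
  invisible(x)
}

#' Flatten edge counts into the 105-measure vector
#'
#' The measure order is the 14 intra counts followed by the 91 inter-pair
#' counts (canonical order), the layout used by the group statistics.
#'
#' @param counts A `community_edge_counts`.
#' @return Named numeric vector of length 105.
#' @export
measure_vector <- function(counts) {
  stopifnot(inherits(counts, "community_edge_counts"))
  c(stats::setNames(as.numeric(counts$intra),
                    paste0("intra:", names(counts$intra))),
    stats::setNames(as.numeric(counts$inter),
                    paste0("inter:", names(counts$inter))))
}

#' Edge counts across a range of graph densities
#'
#' Applies [threshold_proportional()] and [community_edge_counts()] at each
#' density (default the 5%--30% sweep in 5% steps used to check that
#' conclusions are threshold-stable). Because lower densities retain
#' subsets of the edges kept at higher densities, every count is
#' nondecreasing in density.
#'
#' @param C Connectivity matrix.
#' @param partition A `network_partition`.
#' @param densities Numeric vector in `(0, 1]`.
#' @return Named list of `community_edge_counts`, one per density.
#' @export
density_sweep <- function(C, partition,
                          densities = seq(0.05, 0.30, by = 0.05)) {
  stopifnot(all(densities > 0), all(densities <= 1))
  out <- lapply(densities, function(d) {
    community_edge_counts(threshold_proportional(C, d), partition)
  })
  names(out) <- sprintf("%g", densities)
  out
}
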