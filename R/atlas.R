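## Node -> network atlas handling.
##
## Atlas files use 1-based node indices and inclusive ranges exactly as
## published atlas tables print them ("74-83,86-131,137,139"); internal
## storage is a plain integer membership vector.

#' Expand a member-node specification string
#'
#' Turns a comma-separated list of 1-based indices and inclusive ranges
#' (e.g. \code{"74-83,86-131,137,139"}) into a strictly increasing integer
#' vector.
#'
#' @param spec character scalar.
#' @return integer vector of node indices.
#' @keywords internal
expand_node_ranges <- function(spec) {
  parts <- strsplit(trimws(spec), ",", fixed = TRUE)[[1L]]
  parts <- parts[nzchar(parts)]
  if (length(parts) == 0L) stop("empty member-node specification")
  out <- lapply(parts, function(p) {
    if (grepl("-", p, fixed = TRUE)) {
      ab <- as.integer(strsplit(p, "-", fixed = TRUE)[[1L]])
      if (length(ab) != 2L || anyNA(ab) || ab[1L] > ab[2L])
        stop(sprintf("malformed range '%s'", p))
      seq.int(ab[1L], ab[2L])
    } else {
      v <- as.integer(p)
      if (is.na(v)) stop(sprintf("malformed index '%s'", p))
      v
    }
  })
  idx <- unlist(out)
  if (any(idx < 1L)) stop("node indices must be >= 1")
  if (is.unsorted(idx, strictly = TRUE))
    stop(sprintf("member list '%s' is not strictly increasing", spec))
  idx
}

#' Compress node indices back into a range specification
#' @param idx strictly increasing integer vector.
#' @return character scalar in the atlas file dialect.
#' @keywords internal
compress_node_ranges <- function(idx) {
  idx <- as.integer(idx)
  breaks <- c(0L, which(diff(idx) != 1L), length(idx))
  runs <- vapply(seq_len(length(breaks) - 1L), function(k) {
    a <- idx[breaks[k] + 1L]
    b <- idx[breaks[k + 1L]]
    if (a == b) as.character(a) else paste0(a, "-", b)
  }, character(1L))
  paste(runs, collapse = ",")
}

new_atlas <- function(networks, membership) {
  structure(list(
    n_nodes    = length(membership),
    networks   = networks,
    membership = membership
  ), class = "atlas")
}

#' Load a node-to-network atlas table
#'
#' Reads a tab-separated atlas with columns \code{network_index},
#' \code{network_name}, \code{abbreviation} and \code{member_nodes}
#' (comma-separated 1-based indices and inclusive ranges). The networks
#' must partition \code{1..n_nodes} with no overlaps and no gaps; the total
#' node count is inferred as the maximum listed index.
#'
#' @param path path to the atlas TSV.
#' @return an \code{atlas} object: a list with \code{n_nodes},
#'   \code{networks} (data frame with one row per network and a
#'   \code{members} list-column) and \code{membership} (integer vector
#'   mapping each node to its network index).
#' @export
#' @examples
#' atl <- load_atlas(system.file("extdata", "power264_networks.tsv",
#'                               package = "dynmodnet"))
#' atl$n_nodes
load_atlas <- function(path) {
  tab <- read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, colClasses = "character")
  need <- c("network_index", "network_name", "abbreviation", "member_nodes")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("atlas file is missing columns: ", paste(miss, collapse = ", "))
  members <- lapply(tab$member_nodes, expand_node_ranges)
  all_idx <- unlist(members)
  dup <- all_idx[duplicated(all_idx)]
  if (length(dup))
    stop("node(s) assigned to more than one network: ",
         paste(sort(unique(dup)), collapse = ", "))
  n_nodes <- max(all_idx)
  gaps <- setdiff(seq_len(n_nodes), all_idx)
  if (length(gaps))
    stop("node(s) missing from every network: ",
         paste(gaps, collapse = ", "))
  networks <- data.frame(
    network_index = as.integer(tab$network_index),
    network_name  = tab$network_name,
    abbreviation  = tab$abbreviation,
    stringsAsFactors = FALSE
  )
  networks$members <- members
  membership <- integer(n_nodes)
  for (k in seq_len(nrow(networks)))
    membership[members[[k]]] <- networks$network_index[k]
  new_atlas(networks, membership)
}

#' Write an atlas back to the TSV dialect
#'
#' Inverse of \code{\link{load_atlas}}: a written atlas reloads to an
#' identical node-to-network map.
#'
#' @param atlas an \code{atlas} object.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_atlas <- function(atlas, path) {
  stopifnot(inherits(atlas, "atlas"))
  tab <- data.frame(
    network_index = atlas$networks$network_index,
    network_name  = atlas$networks$network_name,
    abbreviation  = atlas$networks$abbreviation,
    member_nodes  = vapply(atlas$networks$members, compress_node_ranges,
                           character(1L)),
    stringsAsFactors = FALSE
  )
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' The 264-node, 14-network functional atlas
#'
#' Loads the bundled whole-brain functional atlas: 264 nodes partitioned
#' into 14 networks (default mode, fronto-parietal, ventral/dorsal
#' attention, salience, visual, auditory, somatomotor, cingulo-opercular,
#' memory retrieval, subcortical, cerebellar, and an uncertain set).
#'
#' @return an \code{atlas} object with 264 nodes and 14 networks.
#' @export
power264_atlas <- function() {
  load_atlas(system.file("extdata", "power264_networks.tsv",
                         package = "dynmodnet", mustWork = TRUE))
}

#' Build a small synthetic atlas
#'
#' Five blocks of contiguous nodes standing in for higher-cognitive
#' (DMN-, FPN-, VAN-like) and sensory (visual, somatomotor) networks; used
#' by the synthetic-cohort generator.
#'
#' @param sizes named integer vector of network sizes; names become
#'   network abbreviations.
#' @return an \code{atlas} object.
#' @export
synthetic_atlas <- function(sizes = c(DMN = 10L, FPN = 8L, VAN = 6L,
                                      VIS = 8L, SSM = 8L)) {
  stopifnot(length(sizes) >= 1L, all(sizes >= 1L))
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  members <- Map(seq.int, starts, ends)
  networks <- data.frame(
    network_index = seq_along(sizes),
    network_name  = names(sizes),
    abbreviation  = names(sizes),
    stringsAsFactors = FALSE
  )
  networks$members <- members
  membership <- rep.int(seq_along(sizes), sizes)
  new_atlas(networks, as.integer(membership))
}

#' @export
print.atlas <- function(x, ...) {
  cat(sprintf("<atlas> %d nodes in %d networks: %s\n", x$n_nodes,
              nrow(x$networks),
              paste(x$networks$abbreviation, collapse = ", ")))
  invisible(x)
}
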