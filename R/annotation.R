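# Fragmentation-tree annotation: glycoside neutral losses and diagnostic
# hydroxycinnamic-acid fragment chains (negative-ion mode) --------------------

GLYCOSIDE_LOSSES <- c(pentose = 132, deoxyhexose = 146, hexose = 162)

# MS2 fragment -> required MS3 children (any one suffices by default)
HCA_SIGNATURES <- list(
  caffeic = list(ms2 = 179, ms3 = 135),
  coumaric = list(ms2 = 163, ms3 = 119),
  quinic = list(ms2 = 191, ms3 = 173),
  ferulic = list(ms2 = 193, ms3 = c(134, 149, 178))
)

#' Build a fragmentation tree
#'
#' @param precursor_mz precursor m/z (negative mode, Da).
#' @param nodes `data.frame` with columns `level` (`"MS2"` or `"MS3"`),
#'   `parent_mz`, `fragment_mz`. Every MS3 node's parent must appear as an
#'   MS2 fragment.
#' @return Object of class `fragment_tree`.
#' @export
fragment_tree <- function(precursor_mz, nodes = NULL) {
  if (precursor_mz <= 0) stop("precursor m/z must be > 0", call. = FALSE)
  if (is.null(nodes))
    nodes <- data.frame(level = character(), parent_mz = numeric(),
                        fragment_mz = numeric())
  nodes <- as.data.frame(nodes)
  need <- c("level", "parent_mz", "fragment_mz")
  if (nrow(nodes) && !all(need %in% names(nodes)))
    stop("nodes need columns level, parent_mz, fragment_mz", call. = FALSE)
  if (nrow(nodes)) {
    if (any(!nodes$level %in% c("MS2", "MS3")))
      stop("levels must be MS2 or MS3", call. = FALSE)
    if (any(nodes$fragment_mz <= 0) || any(nodes$parent_mz <= 0))
      stop("m/z values must be > 0", call. = FALSE)
    ms2_frags <- nodes$fragment_mz[nodes$level == "MS2"]
    ms3 <- nodes[nodes$level == "MS3", ]
    if (nrow(ms3)) {
      orphan <- !vapply(ms3$parent_mz, function(p)
        any(abs(ms2_frags - p) < 1e-6), logical(1))
      if (any(orphan))
        stop("MS3 node(s) whose parent is not an MS2 fragment: m/z ",
             paste(ms3$parent_mz[orphan], collapse = ", "), call. = FALSE)
    }
  }
  structure(list(precursor_mz = precursor_mz, nodes = nodes),
            class = "fragment_tree")
}

# all parent -> child edges of a tree (precursor -> MS2 and MS2 -> MS3)
tree_edges <- function(tree) {
  if (nrow(tree$nodes) == 0)
    return(data.frame(parent = numeric(), fragment = numeric(), level = character()))
  data.frame(parent = tree$nodes$parent_mz, fragment = tree$nodes$fragment_mz,
             level = tree$nodes$level, stringsAsFactors = FALSE)
}

#' Detect glycoside neutral losses
#'
#' Labels every parent-to-fragment mass difference within `tolerance` of
#' 132, 146 or 162 Da as a pentose, deoxyhexose or hexose loss. All edges
#' are considered, both precursor to MS2 and MS2 to MS3.
#'
#' @param tree a [fragment_tree()].
#' @param tolerance mass tolerance in Da (default 0.5, unit resolution).
#' @return `data.frame` with columns `loss`, `sugar`, `parent_mz`,
#'   `fragment_mz`, `level`; zero rows when nothing matches.
#' @export
detect_neutral_losses <- function(tree, tolerance = 0.5) {
  stopifnot(inherits(tree, "fragment_tree"))
  if (tolerance <= 0) stop("tolerance must be > 0", call. = FALSE)
  edges <- tree_edges(tree)
  out <- list()
  for (i in seq_len(nrow(edges))) {
    delta <- edges$parent[i] - edges$fragment[i]
    hit <- which(abs(GLYCOSIDE_LOSSES - delta) <= tolerance)
    for (h in hit)
      out[[length(out) + 1L]] <- data.frame(
        loss = unname(GLYCOSIDE_LOSSES[h]), sugar = names(GLYCOSIDE_LOSSES)[h],
        parent_mz = edges$parent[i], fragment_mz = edges$fragment[i],
        level = edges$level[i], stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(loss = numeric(), sugar = character(),
                      parent_mz = numeric(), fragment_mz = numeric(),
                      level = character()))
  do.call(rbind, out)
}

#' Annotate a hydroxycinnamic-acid derivative class
#'
#' Matches the diagnostic fragment chains: an MS2 fragment of m/z 179 with
#' an MS3 child at 135 marks a caffeic acid derivative; 163 -> 119 coumaric;
#' 191 -> 173 quinic; 193 -> any of 134/149/178 ferulic (set
#' `ferulic_children = "all"` to require all three).
#'
#' @param tree a [fragment_tree()].
#' @param tolerance mass tolerance in Da.
#' @param ferulic_children `"any"` (default) or `"all"`.
#' @return Character vector of matching classes (possibly several, flagged
#'   via attribute `"multiple"`), or `"none"`.
#' @export
annotate_hca_class <- function(tree, tolerance = 0.5,
                               ferulic_children = c("any", "all")) {
  stopifnot(inherits(tree, "fragment_tree"))
  if (tolerance <= 0) stop("tolerance must be > 0", call. = FALSE)
  ferulic_children <- match.arg(ferulic_children)
  nodes <- tree$nodes
  hits <- character()
  for (cls in names(HCA_SIGNATURES)) {
    sig <- HCA_SIGNATURES[[cls]]
    ms2 <- nodes[nodes$level == "MS2" &
                   abs(nodes$fragment_mz - sig$ms2) <= tolerance, ]
    if (!nrow(ms2)) next
    found <- FALSE
    for (fmz in ms2$fragment_mz) {
      children <- nodes$fragment_mz[nodes$level == "MS3" &
                                      abs(nodes$parent_mz - fmz) <= tolerance]
      if (!length(children)) next
      match_child <- vapply(sig$ms3, function(m)
        any(abs(children - m) <= tolerance), logical(1))
      ok <- if (cls == "ferulic" && ferulic_children == "all")
        all(match_child) else any(match_child)
      if (ok) { found <- TRUE; break }
    }
    if (found) hits <- c(hits, cls)
  }
  if (!length(hits)) return("none")
  structure(hits, multiple = length(hits) > 1)
}
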