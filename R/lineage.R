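## Lineage trees: construction, canonical ordering, sublineage enumeration.

# canonical depth-first order, children in lexicographic (radix) name order
.dfsOrder <- function(cell, parent) {
  n <- length(cell)
  kids <- split(seq_len(n), factor(parent, levels = cell))
  root <- which(is.na(parent))
  out <- integer(n)
  k <- 0L
  stack <- root
  while (length(stack) > 0L) {
    i <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    k <- k + 1L
    out[k] <- i
    ch <- kids[[cell[i]]]
    if (length(ch) > 0L) {
      ch <- ch[order(cell[ch], method = "radix", decreasing = TRUE)]
      stack <- c(stack, ch)
    }
  }
  out[seq_len(k)]
}

.newLineageTree <- function(cell, parent, terminal) {
  df <- data.frame(cell = as.character(cell),
                   parent = as.character(parent),
                   terminal = as.logical(terminal),
                   stringsAsFactors = FALSE)
  ord <- .dfsOrder(df$cell, df$parent)
  if (length(ord) != nrow(df))
    stop("lineage table contains cells unreachable from the root ",
         "(orphaned subtree or cycle)")
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  new("LineageTree", cells = df)
}

# list of integer children indices per cell, in tree order
.childrenList <- function(tree) {
  df <- tree@cells
  split(seq_len(nrow(df)), factor(df$parent, levels = df$cell))
}

# logical mask over cells (tree order) of the subtree rooted at index i
.subtreeMask <- function(tree, i, kids = .childrenList(tree)) {
  n <- nrow(tree@cells)
  mask <- logical(n)
  stack <- i
  while (length(stack) > 0L) {
    j <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    mask[j] <- TRUE
    stack <- c(stack, kids[[tree@cells$cell[j]]])
  }
  mask
}

#' Load a lineage tree from a parent table
#'
#' Builds a [LineageTree-class] from a table with one row per cell giving its
#' name, its parent's name (empty or NA for the root) and whether it is a
#' terminal cell. Cells are re-ordered into the canonical depth-first order
#' (children in lexicographic name order) that defines sort-matrix columns.
#'
#' @param table a data.frame with columns \code{cell}, \code{parent},
#'   \code{terminal} (0/1 or logical), or the path of a TSV file with those
#'   columns.
#' @return a validated [LineageTree-class].
#' @examples
#' tab <- data.frame(cell = c("P0", "AB", "P1"),
#'                   parent = c(NA, "P0", "P0"),
#'                   terminal = c(0, 1, 1))
#' loadLineage(tab)
#' @export
loadLineage <- function(table) {
  if (is.character(table) && length(table) == 1L) {
    if (!file.exists(table)) stop("lineage file not found: ", table)
    table <- utils::read.delim(table, stringsAsFactors = FALSE)
  }
  if (!is.data.frame(table) || nrow(table) == 0L)
    stop("lineage table must be a non-empty data.frame")
  need <- c("cell", "parent", "terminal")
  if (!all(need %in% names(table)))
    stop("lineage table must have columns: ", paste(need, collapse = ", "))
  cell <- as.character(table$cell)
  parent <- as.character(table$parent)
  parent[is.na(parent) | parent == ""] <- NA_character_
  terminal <- as.logical(as.integer(as.logical(table$terminal) |
                                      table$terminal %in% c(1, "1")))
  if (anyDuplicated(cell))
    stop(sprintf("duplicate cell name '%s' at row %d",
                 cell[duplicated(cell)][1L], which(duplicated(cell))[1L]))
  orphan <- !is.na(parent) & !(parent %in% cell)
  if (any(orphan))
    stop(sprintf("row %d: parent '%s' of cell '%s' not present in table",
                 which(orphan)[1L], parent[orphan][1L], cell[orphan][1L]))
  if (sum(is.na(parent)) != 1L)
    stop(sprintf("table must contain exactly one root row (found %d)",
                 sum(is.na(parent))))
  # explicit cycle detection with row attribution
  pidx <- match(parent, cell)
  for (i in seq_along(cell)) {
    slow <- i; fast <- i; repeat {
      fast <- pidx[fast]; if (is.na(fast)) break
      fast <- pidx[fast]; if (is.na(fast)) break
      slow <- pidx[slow]
      if (slow == fast)
        stop(sprintf("cycle detected: cell '%s' (row %d) is its own ancestor",
                     cell[i], i))
    }
  }
  tree <- .newLineageTree(cell, parent, terminal)
  validObject(tree)
  tree
}

#' Load a symmetry map from a pair table
#'
#' @param table data.frame (or TSV path) with columns \code{left_root} and
#'   \code{right_root}, one row per left-right symmetric sublineage pair.
#' @param tree optional [LineageTree-class]; if given, pair roots are checked
#'   against it.
#' @return a [SymmetryMap-class].
#' @export
loadSymmetryMap <- function(table, tree = NULL) {
  if (is.character(table) && length(table) == 1L) {
    if (!file.exists(table)) stop("symmetry file not found: ", table)
    table <- utils::read.delim(table, stringsAsFactors = FALSE)
  }
  need <- c("left_root", "right_root")
  if (!all(need %in% names(table)))
    stop("symmetry table must have columns: ", paste(need, collapse = ", "))
  sm <- new("SymmetryMap",
            pairs = data.frame(left_root = as.character(table$left_root),
                               right_root = as.character(table$right_root),
                               stringsAsFactors = FALSE))
  if (!is.null(tree)) {
    unknown <- setdiff(c(sm@pairs$left_root, sm@pairs$right_root),
                       cellNames(tree))
    if (length(unknown) > 0L)
      stop("symmetry pair root not in tree: ", unknown[1L])
  }
  validObject(sm)
  sm
}

#' Generate a synthetic mirrored lineage tree
#'
#' Builds a binary tree with two mirror-image subtrees hanging off a shared
#' root, emulating the left-right symmetry of real invariant lineages. Each
#' side has \code{nLeafPairs} terminal cells; with \code{depthJitter = 0} the
#' sides are as balanced as possible (complete when \code{nLeafPairs} is a
#' power of two), and positive jitter randomizes which leaf is split at each
#' growth step, producing irregular depths. The returned [SymmetryMap-class]
#' pairs every left-side cell with its mirror on the right.
#'
#' @param nLeafPairs number of terminal-cell pairs (>= 1).
#' @param depthJitter non-negative integer; 0 gives a deterministic balanced
#'   topology, larger values give increasingly random topologies.
#' @param seed integer seed for reproducibility.
#' @return list with elements \code{tree} ([LineageTree-class]) and
#'   \code{symmetry} ([SymmetryMap-class]).
#' @examples
#' syn <- generateSyntheticLineage(4, depthJitter = 0, seed = 1)
#' syn$tree
#' @export
generateSyntheticLineage <- function(nLeafPairs, depthJitter = 0L, seed = 1L) {
  if (nLeafPairs < 1) stop("nLeafPairs must be >= 1")
  if (depthJitter < 0) stop("depthJitter must be >= 0")
  set.seed(seed)
  # grow one side: start from a single leaf "", split leaves until nLeafPairs.
  # names are "a"/"p" (anterior/posterior) suffix strings.
  leaves <- ""
  internal <- character(0)
  while (length(leaves) < nLeafPairs) {
    if (depthJitter > 0) {
      # favor shallow leaves less as jitter grows: uniform choice is maximal
      # irregularity; mix between balanced (shortest-name) and uniform
      if (stats::runif(1) < min(1, depthJitter / (depthJitter + 1))) {
        pick <- sample.int(length(leaves), 1L)
      } else {
        pick <- which.min(nchar(leaves))
      }
    } else {
      pick <- which.min(nchar(leaves))
    }
    nm <- leaves[pick]
    internal <- c(internal, nm)
    leaves <- c(leaves[-pick], paste0(nm, "a"), paste0(nm, "p"))
  }
  suffixes <- c(internal, leaves)
  is_term <- c(rep(FALSE, length(internal)), rep(TRUE, length(leaves)))
  sideCells <- function(prefix) {
    nm <- paste0(prefix, suffixes)
    par <- ifelse(suffixes == "", "P0",
                  paste0(prefix, substr(suffixes, 1L,
                                        nchar(suffixes) - 1L)))
    data.frame(cell = nm, parent = par, terminal = is_term,
               stringsAsFactors = FALSE)
  }
  df <- rbind(data.frame(cell = "P0", parent = NA_character_,
                         terminal = FALSE, stringsAsFactors = FALSE),
              sideCells("L"), sideCells("R"))
  tree <- .newLineageTree(df$cell, df$parent, df$terminal)
  validObject(tree)
  sym <- new("SymmetryMap",
             pairs = data.frame(left_root = paste0("L", suffixes),
                                right_root = paste0("R", suffixes),
                                stringsAsFactors = FALSE))
  list(tree = tree, symmetry = sym)
}

#' Boolean mask of a rooted sublineage
#'
#' @param tree a [LineageTree-class].
#' @param rootName name of the sublineage root cell.
#' @return logical vector over cells in tree order, TRUE exactly on the cell
#'   and all of its descendants.
#' @export
lineageMask <- function(tree, rootName) {
  i <- match(rootName, cellNames(tree))
  if (is.na(i)) stop("unknown cell name: ", rootName)
  mask <- .subtreeMask(tree, i)
  names(mask) <- cellNames(tree)
  mask
}

# subtree size per cell under either counting convention
.subtreeSizes <- function(tree, count = c("all", "terminal")) {
  count <- match.arg(count)
  df <- tree@cells
  n <- nrow(df)
  pidx <- match(df$parent, df$cell)
  size <- if (count == "all") rep(1L, n) else as.integer(df$terminal)
  # rows are in DFS order, so children come after parents: accumulate bottom-up
  for (i in rev(seq_len(n))) {
    if (!is.na(pidx[i])) size[pidx[i]] <- size[pidx[i]] + size[i]
  }
  size
}

#' Enumerate sublineages with a minimum size
#'
#' Returns one mask per cell whose rooted subtree contains at least
#' \code{minCells} cells. By default all cells of the subtree (root, internal
#' and terminal) are counted, since the sort matrix carries one column per
#' cell; set \code{count = "terminal"} to count terminal cells only.
#'
#' @param tree a [LineageTree-class].
#' @param minCells minimum subtree size (>= 1).
#' @param count counting convention, \code{"all"} (default) or
#'   \code{"terminal"}.
#' @return named list of logical cell-masks, ordered by tree index of the
#'   sublineage root.
#' @export
sublineages <- function(tree, minCells = 1L, count = c("all", "terminal")) {
  count <- match.arg(count)
  if (minCells < 1) stop("minCells must be >= 1")
  sizes <- .subtreeSizes(tree, count)
  keep <- which(sizes >= minCells)
  kids <- .childrenList(tree)
  masks <- lapply(keep, function(i) {
    m <- .subtreeMask(tree, i, kids)
    names(m) <- cellNames(tree)
    m
  })
  names(masks) <- cellNames(tree)[keep]
  masks
}

#' Enumerate symmetric-pair sublineages with a minimum size
#'
#' One mask per left-right pair in which BOTH sublineages contain at least
#' \code{minCells} cells; the mask is the union of the two sublineages.
#'
#' @param tree a [LineageTree-class].
#' @param sym a [SymmetryMap-class].
#' @param minCells minimum per-side subtree size.
#' @param count counting convention as in [sublineages()].
#' @return named list of logical cell-masks (names
#'   \code{"left|right"}).
#' @export
symmetricPairSublineages <- function(tree, sym, minCells = 1L,
                                     count = c("all", "terminal")) {
  count <- match.arg(count)
  sizes <- .subtreeSizes(tree, count)
  nm <- cellNames(tree)
  kids <- .childrenList(tree)
  out <- list()
  for (r in seq_len(nrow(sym@pairs))) {
    li <- match(sym@pairs$left_root[r], nm)
    ri <- match(sym@pairs$right_root[r], nm)
    if (is.na(li) || is.na(ri))
      stop("symmetry pair root not in tree: ",
           if (is.na(li)) sym@pairs$left_root[r] else sym@pairs$right_root[r])
    if (sizes[li] >= minCells && sizes[ri] >= minCells) {
      m <- .subtreeMask(tree, li, kids) | .subtreeMask(tree, ri, kids)
      names(m) <- nm
      out[[paste0(nm[li], "|", nm[ri])]] <- m
    }
  }
  out
}
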