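#' Rooted tree with per-node karyotypes
#'
#' Couples an `ape` phylogeny (internal nodes labelled) with a wide bin
#' table holding one integer copy-number column per tip and internal-node
#' label, so that CNA events can be read off every branch.
#'
#' @param phy An `ape::phylo`, rooted, with `node.label` set.
#' @param karyotypes Wide bin table whose sample columns cover every tip and
#'   node label of `phy`.
#' @return Object of class `"event_tree"`.
#' @export
event_tree <- function(phy, karyotypes) {
  if (!inherits(phy, "phylo")) abort("phy must be an ape phylo")
  # single root: exactly one node never appears as a child (multifurcating
  # roots, as in minimum-event CN trees, are fine)
  n_roots <- sum(!(unique(phy$edge[, 1]) %in% phy$edge[, 2]))
  if (n_roots != 1) abort("phy must have a single root")
  if (is.null(phy$node.label) || anyNA(phy$node.label) ||
      any(phy$node.label == "")) {
    abort("phy must carry labels for every internal node")
  }
  labels <- c(phy$tip.label, phy$node.label)
  missing <- setdiff(labels, sample_cols(karyotypes))
  if (length(missing) > 0) {
    abort(paste("karyotypes missing for:", paste(missing, collapse = ", ")))
  }
  structure(list(phy = phy, karyotypes = karyotypes), class = "event_tree")
}

#' CNA events on one branch
#'
#' Maximal contiguous runs of bins (within chromosomes) where the child copy
#' number exceeds the parent give one gain event each, and runs below give
#' one loss event each; an event is counted once regardless of the magnitude
#' of the copy-number change.
#'
#' @param parent,child One-sample bin tables on a shared grid (or numeric
#'   vectors with `grid` supplied).
#' @param grid Bin grid, required when vectors are given.
#' @return Tibble: `chrom`, `start`, `end`, `start_bin`, `end_bin`,
#'   `direction`.
#' @export
branch_events <- function(parent, child, grid = NULL) {
  if (is.data.frame(parent)) {
    check_shared_grid(parent, child)
    grid <- parent[c("chrom", "start", "end")]
    parent <- as.numeric(cn_matrix(parent))
    child <- as.numeric(cn_matrix(child))
  }
  if (is.null(grid)) abort("grid required when karyotypes are vectors")
  if (length(parent) != length(child) || length(parent) != nrow(grid)) {
    abort("karyotypes must match the grid length")
  }
  branch_events_vec(parent, child, grid)
}

branch_events_vec <- function(pv, cv, grid) {
  ch <- chrom_index(grid)
  s <- sign(cv - pv)
  n <- length(s)
  # run starts where the (state, chrom) pair changes
  new_run <- c(TRUE, s[-1] != s[-n] | ch[-1] != ch[-n])
  run_id <- cumsum(new_run)
  keep <- s != 0
  if (!any(keep)) {
    return(tibble::tibble(chrom = character(0), start = numeric(0),
                          end = numeric(0), start_bin = integer(0),
                          end_bin = integer(0), direction = character(0)))
  }
  idx <- split(which(keep), run_id[keep])
  purrr::map_dfr(idx, function(i) {
    tibble::tibble(chrom = grid$chrom[i[1]], start = grid$start[i[1]],
                   end = grid$end[i[length(i)]],
                   start_bin = i[1], end_bin = i[length(i)],
                   direction = if (s[i[1]] > 0) "gain" else "loss")
  })
}

#' Classify tree CNA events as clonal, intermediate or tip
#'
#' Events on the path from the root to the most recent common ancestor
#' (MRCA) of the tumor-sample leaves are clonal; events on internal branches
#' below the MRCA are intermediate; events on pendant (leaf) branches are
#' tip events. Leaves not listed in `samples` (e.g. a normal outgroup) are
#' excluded from the MRCA and their branches are not classified.
#'
#' @param x An [event_tree()].
#' @param samples Tip labels of the tumor samples (default: all tips).
#' @return Tibble of events: `branch` (child label), `category`, plus the
#'   [branch_events()] columns.
#' @export
classify_events <- function(x, samples = NULL) {
  phy <- x$phy
  samples <- samples %||% phy$tip.label
  if (length(samples) < 2) abort("need >= 2 sample leaves (MRCA undefined)")
  if (!all(samples %in% phy$tip.label)) abort("unknown sample leaves")
  ntip <- length(phy$tip.label)
  root <- ntip + 1L
  labels <- c(phy$tip.label, phy$node.label)
  mrca <- ape::getMRCA(phy, samples)
  path_nodes <- ape::nodepath(phy, root, mrca)
  # nodes in the MRCA subtree restricted to sampled leaves' lineage
  desc <- descendant_nodes(phy, mrca)
  m <- cn_matrix(x$karyotypes)
  grid <- x$karyotypes[c("chrom", "start", "end")]
  sample_nodes <- match(samples, phy$tip.label)
  out <- purrr::map_dfr(seq_len(nrow(phy$edge)), function(e) {
    p <- phy$edge[e, 1]; c_ <- phy$edge[e, 2]
    category <- if (c_ %in% path_nodes) "clonal"
      else if (c_ %in% desc && c_ <= ntip && c_ %in% sample_nodes) "tip"
      else if (c_ %in% desc && c_ > ntip) "intermediate"
      else NA_character_
    if (is.na(category)) return(NULL)
    ev <- branch_events_vec(m[, labels[p]], m[, labels[c_]], grid)
    if (nrow(ev) == 0) return(NULL)
    dplyr::mutate(ev, branch = labels[c_], category = category,
                  .before = 1)
  })
  if (nrow(out) == 0) {
    out <- tibble::tibble(branch = character(0), category = character(0),
                          chrom = character(0), start = numeric(0),
                          end = numeric(0), start_bin = integer(0),
                          end_bin = integer(0), direction = character(0))
  }
  out
}

descendant_nodes <- function(phy, node) {
  kids <- phy$edge[phy$edge[, 1] == node, 2]
  if (length(kids) == 0) return(integer(0))
  c(kids, unlist(lapply(kids, descendant_nodes, phy = phy)))
}

#' Per-bin CNA event frequencies across patients
#'
#' Fraction of patients (trees) carrying at least one gain and at least one
#' loss overlapping each bin, separately for a given event category. Clonal
#' events are normalised to the patient ploidy: the MRCA karyotype is
#' compared against the rounded patient ploidy (round half up) rather than
#' the root baseline, so a uniformly triploid or tetraploid genome does not
#' read as all-gained.
#'
#' @param trees List of [event_tree()] objects (one per patient).
#' @param category `"clonal"`, `"intermediate"` or `"tip"`.
#' @param ploidy Numeric vector of patient ploidies (required for
#'   `"clonal"`), recycled if length 1.
#' @param samples Optional list of tumor-leaf label vectors, parallel to
#'   `trees`.
#' @return Bin table with `gain_freq` and `loss_freq` columns.
#' @export
event_frequency <- function(trees, category = c("clonal", "intermediate",
                                                "tip"),
                            ploidy = NULL, samples = NULL) {
  category <- match.arg(category)
  if (category == "clonal" && is.null(ploidy)) {
    abort("patient ploidy required for clonal frequencies")
  }
  if (!is.null(ploidy)) ploidy <- rep_len(ploidy, length(trees))
  grid <- trees[[1]]$karyotypes[c("chrom", "start", "end")]
  nb <- nrow(grid)
  gains <- losses <- matrix(FALSE, nb, length(trees))
  for (i in seq_along(trees)) {
    tr <- trees[[i]]
    check_shared_grid(tr$karyotypes, grid)
    sm <- if (is.null(samples)) NULL else samples[[i]]
    if (category == "clonal") {
      phy <- tr$phy
      labels <- c(phy$tip.label, phy$node.label)
      mrca <- ape::getMRCA(phy, sm %||% phy$tip.label)
      kary <- cn_matrix(tr$karyotypes)[, labels[mrca]]
      base <- floor(ploidy[i] + 0.5)
      gains[, i] <- kary > base
      losses[, i] <- kary < base
    } else {
      ev <- classify_events(tr, samples = sm)
      ev <- dplyr::filter(ev, .data$category == !!category)
      for (r in seq_len(nrow(ev))) {
        rng <- ev$start_bin[r]:ev$end_bin[r]
        if (ev$direction[r] == "gain") gains[rng, i] <- TRUE
        else losses[rng, i] <- TRUE
      }
    }
  }
  dplyr::mutate(tibble::as_tibble(grid),
                gain_freq = rowMeans(gains), loss_freq = rowMeans(losses))
}

#' Event tree of sampled glands from a simulation
#'
#' Builds the karyotype-lineage tree of a set of sampled glands: one tip per
#' gland, internal nodes at the clones ancestral to the sample (unary chains
#' collapsed), plus a `"founder"` outgroup tip carrying the founder
#' karyotype so the root-to-MRCA branch is observable.
#'
#' @param sim A `"cin_sim"`.
#' @param glands Output of [sample_glands()] (carries clone indices).
#' @return An [event_tree()]; tumor tips are the gland ids, the outgroup tip
#'   is `"founder"`.
#' @export
as_event_tree <- function(sim, glands) {
  clones <- attr(glands, "clones")
  if (is.null(clones)) abort("glands must come from sample_glands()")
  gland_ids <- sample_cols(glands)
  # ancestor chains; founder clones have parent 0
  chains <- lapply(unique(clones), function(cl) {
    ch <- integer(0); i <- cl
    while (i != 0L) { ch <- c(i, ch); i <- sim$parent[i] }
    ch
  })
  roots <- unique(vapply(chains, `[`, 0L, 1))
  if (length(roots) > 1) {
    abort("sampled glands do not share a recorded founder clone")
  }
  node_set <- sort(unique(unlist(chains)))
  root_clone <- roots[1]
  nearest_anc <- function(cl) {
    i <- sim$parent[cl]
    while (i != 0L && !(i %in% node_set)) i <- sim$parent[i]
    i
  }
  ntip <- length(gland_ids) + 1L # + founder outgroup
  node_order <- c(root_clone, setdiff(node_set, root_clone))
  node_num <- setNames(ntip + seq_along(node_order), node_order)
  edges <- matrix(0L, 0, 2)
  for (cl in node_set) {
    if (cl == root_clone) next
    a <- nearest_anc(cl)
    edges <- rbind(edges, c(node_num[[as.character(a)]],
                            node_num[[as.character(cl)]]))
  }
  for (g in seq_along(gland_ids)) {
    edges <- rbind(edges, c(node_num[[as.character(clones[g])]], g))
  }
  edges <- rbind(edges, c(ntip + 1L, ntip)) # founder outgroup tip
  storage.mode(edges) <- "integer"
  phy <- list(edge = edges, tip.label = c(gland_ids, "founder"),
              node.label = paste0("c", node_order),
              Nnode = length(node_order))
  class(phy) <- "phylo"
  phy <- ape::collapse.singles(phy)
  labels <- c(phy$tip.label, phy$node.label)
  km <- matrix(0, nrow(sim$grid), length(labels),
               dimnames = list(NULL, labels))
  for (g in seq_along(gland_ids)) km[, gland_ids[g]] <- sim$kary[clones[g], ]
  km[, "founder"] <- sim$kary[root_clone, ]
  for (lb in phy$node.label) {
    cl <- as.integer(sub("^c", "", lb))
    km[, lb] <- sim$kary[cl, ]
  }
  event_tree(phy, bin_table(sim$grid, km))
}
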