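## Uniparental haplogroup calling: variant status from reads, mtDNA
## haplogroup scoring from a consensus, and parsimony placement on a
## haplogroup tree.

#' Haplogroup definitions: a rooted tree plus branch-defining variants
#'
#' @param tree a rooted `ape::phylo` with tip and node labels naming the
#'   haplogroups.
#' @param variants data.frame with columns `branch` (child-node label of the
#'   branch the variant defines), `pos` (1-based position), `anc`, `der`
#'   (ancestral/derived bases).
#' @param contig contig the variants live on.
#' @return An object of class `haplo_defs`.
#' @export
haplo_defs <- function(tree, variants, contig = "MT") {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("haplo_defs: tree must be rooted")
  if (is.null(tree$node.label) || any(tree$node.label == "")) {
    stop("haplo_defs: tree needs node labels (basal haplogroup names)")
  }
  labels <- c(tree$tip.label, tree$node.label)
  if (anyDuplicated(labels)) stop("haplo_defs: duplicated haplogroup names")
  bad <- setdiff(unique(variants$branch), labels)
  if (length(bad)) {
    stop("haplo_defs: variants reference unknown branch(es): ",
         paste(bad, collapse = ", "))
  }
  dup <- stats::aggregate(pos ~ branch, variants, anyDuplicated)
  if (any(dup$pos > 0)) stop("haplo_defs: duplicated positions within a branch")
  structure(list(tree = tree, variants = variants, contig = contig),
            class = "haplo_defs")
}

haplo_labels <- function(defs) c(defs$tree$tip.label, defs$tree$node.label)

## Root-to-node path (node names, root excluded) for a haplogroup name.
haplo_path <- function(defs, name) {
  labels <- haplo_labels(defs)
  id <- match(name, labels)
  if (is.na(id)) stop("unknown haplogroup: ", name)
  root <- ape::Ntip(defs$tree) + 1L
  if (id == root) return(character(0))
  labels[ape::nodepath(defs$tree, root, id)[-1]]
}

haplo_root <- function(defs) {
  haplo_labels(defs)[ape::Ntip(defs$tree) + 1L]
}

## Variant row indices defining the root-to-`name` path.
path_variant_idx <- function(defs, name) {
  which(defs$variants$branch %in% haplo_path(defs, name))
}

#' Ancestral/derived status of haplogroup-defining variants from reads
#'
#' Each variant is `derived` or `ancestral` when all passing read bases agree
#' with that allele, `conflict` when both alleles are observed, and `missing`
#' when no passing read covers it (bases matching neither allele are treated
#' as sequencing noise and ignored). With `damage_mask = TRUE`, C-to-T and
#' G-to-A defining variants are masked to `missing`: in unrepaired ancient
#' libraries post-mortem deamination can fake the derived state of such
#' variants.
#'
#' @param rs an [aln_reads] object.
#' @param defs a [haplo_defs] object (or a bare variants data.frame plus
#'   `contig`).
#' @param min_bq,min_mapq base / mapping quality filters.
#' @param damage_mask mask deamination-mimicking variants (default TRUE).
#' @param contig used only when `defs` is a bare data.frame.
#' @return The variants data.frame with an added `status` column.
#' @export
snp_status <- function(rs, defs, min_bq = 30L, min_mapq = 30L,
                       damage_mask = TRUE, contig = "MT") {
  variants <- if (inherits(defs, "haplo_defs")) defs$variants else defs
  if (inherits(defs, "haplo_defs")) contig <- defs$contig
  pb <- pileup_bases(rs, contig, variants$pos, min_mapq = min_mapq,
                     min_bq = min_bq)
  n_der <- n_anc <- integer(nrow(variants))
  if (nrow(pb)) {
    n_der <- vapply(seq_len(nrow(variants)), function(i) {
      sum(pb$site == i & pb$base == variants$der[i])
    }, integer(1))
    n_anc <- vapply(seq_len(nrow(variants)), function(i) {
      sum(pb$site == i & pb$base == variants$anc[i])
    }, integer(1))
  }
  status <- rep("missing", nrow(variants))
  status[n_der > 0 & n_anc == 0] <- "derived"
  status[n_anc > 0 & n_der == 0] <- "ancestral"
  status[n_anc > 0 & n_der > 0] <- "conflict"
  if (damage_mask) {
    deam <- (variants$anc == "C" & variants$der == "T") |
      (variants$anc == "G" & variants$der == "A")
    status[deam] <- "missing"
  }
  out <- variants
  out$status <- status
  out
}

#' Score mtDNA haplogroups against observed derived variants
#'
#' Kulczynski-style scoring: for candidate haplogroup `h` with expected
#' root-to-h variant set `E`, observed derived set `O` and covered set `C`,
#' `score = ((|E & O| / |E & C|) + (|E & O| / |O|)) / 2`. The first term
#' rewards finding the expected variants (among those the data could have
#' seen); the second penalises observed derived variants the haplogroup does
#' not expect. Candidates are ranked descending with deterministic
#' tie-breaks: deeper haplogroup first, then name.
#'
#' @param derived_pos positions observed in the derived state.
#' @param covered_pos positions with a confident base call (used to restrict
#'   `E` to testable variants).
#' @param defs a [haplo_defs] object.
#' @return data.frame of candidates with `haplogroup`, `score`, `n_support`,
#'   `n_expected_covered`, `depth`, ranked best-first. With no observed
#'   derived variants, the root is returned with `score = NA`.
#' @export
assign_mt_haplogroup <- function(derived_pos, covered_pos, defs) {
  labels <- haplo_labels(defs)
  if (length(derived_pos) == 0L) {
    return(data.frame(haplogroup = haplo_root(defs), score = NA_real_,
                      n_support = 0L, n_expected_covered = 0L, depth = 0L))
  }
  rows <- lapply(labels, function(h) {
    e_idx <- path_variant_idx(defs, h)
    e_pos <- defs$variants$pos[e_idx]
    e_cov <- intersect(e_pos, covered_pos)
    hit <- intersect(e_pos, derived_pos)
    score <- if (length(e_cov) == 0L) NA_real_ else {
      0.5 * (length(hit) / length(e_cov) + length(hit) / length(derived_pos))
    }
    data.frame(haplogroup = h, score = score, n_support = length(hit),
               n_expected_covered = length(e_cov),
               depth = length(haplo_path(defs, h)))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-ifelse(is.na(out$score), -Inf, out$score), -out$depth,
                   out$haplogroup), ]
  rownames(out) <- NULL
  out
}

#' Convenience: mtDNA haplogroup call from a consensus sequence
#'
#' Reads each defining variant's base off the consensus (N = uncovered) and
#' delegates to [assign_mt_haplogroup()].
#'
#' @param consensus consensus sequence string (see [mt_consensus()]).
#' @param defs a [haplo_defs] object.
#' @return As [assign_mt_haplogroup()].
#' @export
mt_haplogroup_from_consensus <- function(consensus, defs) {
  v <- defs$variants
  base <- substring(consensus, v$pos, v$pos)
  assign_mt_haplogroup(derived_pos = v$pos[base == v$der],
                       covered_pos = v$pos[base != "N" & base != ""],
                       defs = defs)
}

#' Parsimony placement of a sample on the haplogroup tree
#'
#' Maximises (derived support - conflicts) over all root-to-node paths, where
#' support counts path variants observed derived and conflicts counts path
#' variants observed ancestral (or in within-sample conflict). Internal nodes
#' are legitimate answers: a sample carrying only the shared derived variants
#' of a clade places basally on that clade rather than being forced to a
#' leaf. Ties prefer the shallower (more conservative) node, then the name.
#'
#' @param statuses output of [snp_status()].
#' @param defs a [haplo_defs] object.
#' @return A list of class `haplo_call`: `haplogroup`, `score`,
#'   `n_derived_support`, `n_conflicts`, `n_missing`, `margin` (score gap to
#'   the runner-up), and the full per-node table.
#' @export
place_on_tree <- function(statuses, defs) {
  if (all(statuses$status == "missing")) {
    stop("place_on_tree: no informative sites")
  }
  labels <- haplo_labels(defs)
  key <- paste(statuses$branch, statuses$pos)
  tab <- do.call(rbind, lapply(labels, function(h) {
    idx <- match(paste(defs$variants$branch, defs$variants$pos)[
      path_variant_idx(defs, h)], key)
    st <- statuses$status[idx]
    data.frame(haplogroup = h,
               support = sum(st %in% "derived"),
               conflicts = sum(st %in% c("ancestral", "conflict")),
               depth = length(haplo_path(defs, h)))
  }))
  tab$score <- tab$support - tab$conflicts
  tab <- tab[order(-tab$score, tab$depth, tab$haplogroup), ]
  rownames(tab) <- NULL
  best <- tab[1, ]
  structure(list(
    haplogroup = best$haplogroup,
    score = best$score,
    n_derived_support = best$support,
    n_conflicts = best$conflicts,
    n_missing = sum(statuses$status == "missing"),
    margin = if (nrow(tab) > 1) best$score - tab$score[2] else NA_real_,
    table = tab
  ), class = "haplo_call")
}

#' @export
print.haplo_call <- function(x, ...) {
  cat(sprintf(
    "<haplo_call> %s (score %s; support %d, conflicts %d, missing %d, margin %s)\n",
    x$haplogroup, format(x$score), x$n_derived_support, x$n_conflicts,
    x$n_missing, format(x$margin)))
  invisible(x)
}
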