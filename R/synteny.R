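## Synteny-based gene-status calls: distinguishing true gene loss from
## assembly artifacts. A gene is called ABSENT only when its conserved
## flanking marker genes co-occur on one contig, close together, with no
## trace of the target between them — otherwise the evidence is insufficient
## and the call is UNDETERMINED.

#' A flanking-marker rule for one target family
#'
#' Conserved flanking markers (e.g. `NOL9`/`ZBTB48` around `Tas1r1`,
#' `MIB2`/`GOLIM4` around `Tas1r2`, `DVL1`/`CPTP` around `Tas1r3`) used to
#' call true absence of the target.
#'
#' @param target target gene family, e.g. `"Tas1r1"`.
#' @param upstream,downstream marker gene symbols, distinct from the target.
#' @param max_span maximum distance (nt) between the two markers on one
#'   contig for an absence call; the default 1 Mb is conservative.
#' @return object of class `marker_rule`.
#' @export
marker_rule <- function(target, upstream, downstream, max_span = 1e6) {
  if (target %in% c(upstream, downstream))
    .stopf("markers must be distinct from the target")
  structure(list(target = target, upstream = upstream,
                 downstream = downstream, max_span = max_span),
            class = "marker_rule")
}

#' Call the status of a target gene from models, hits and marker synteny
#'
#' `PRESENT` when an intact model of the target exists; `PSEUDOGENE` when
#' only pseudogene (or short/partial) models exist; `ABSENT` when no target
#' locus was found and both flanking markers lie on the same contig within
#' `rule$max_span` with no target hit between them; `UNDETERMINED` otherwise
#' (markers missing or split across contigs). In `"permissive"` mode a
#' same-contig marker pair qualifies regardless of whether the two markers
#' are each other's neighbours within `max_span`; `"strict"` mode (default)
#' requires the pair within `max_span`.
#'
#' @param models `gene_models` for the target family in this species (may
#'   have zero rows).
#' @param hits `search_hits` for the target in this species (used to check
#'   the inter-marker interval; may have zero rows).
#' @param marker_annotations data frame with columns `marker`, `contig`,
#'   `start`, `end` (0-based half-open).
#' @param rule a [marker_rule()].
#' @param mode `"strict"` or `"permissive"`.
#' @return one of `"PRESENT"`, `"PSEUDOGENE"`, `"ABSENT"`, `"UNDETERMINED"`.
#' @export
call_gene_status <- function(models, hits, marker_annotations, rule,
                             mode = c("strict", "permissive")) {
  mode <- match.arg(mode)
  need <- c("marker", "contig", "start", "end")
  if (!all(need %in% names(marker_annotations)))
    .stopf("marker annotations need columns: %s", paste(need, collapse = ", "))
  if (nrow(models) > 0L) {
    if (any(models$category == "INTACT")) return("PRESENT")
    return("PSEUDOGENE")
  }
  up <- marker_annotations[marker_annotations$marker == rule$upstream, , drop = FALSE]
  dn <- marker_annotations[marker_annotations$marker == rule$downstream, , drop = FALSE]
  if (nrow(up) == 0L || nrow(dn) == 0L) return("UNDETERMINED")
  for (i in seq_len(nrow(up))) for (j in seq_len(nrow(dn))) {
    if (up$contig[i] != dn$contig[j]) next
    lo <- min(up$start[i], dn$start[j]); hi <- max(up$end[i], dn$end[j])
    if (mode == "strict" && hi - lo > rule$max_span) next
    between <- nrow(hits) > 0L &&
      any(hits$contig == up$contig[i] & hits$end > lo & hits$start < hi)
    if (!between) return("ABSENT")
  }
  "UNDETERMINED"
}
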