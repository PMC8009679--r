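## Concordance between VCF-predicted residue-pair movements and
## beta-carbon distance changes measured on structural models of the
## closed, open and desensitized states of the trimeric channel.
##
## A negative dF of a fluorophore-quencher pair indicates increased
## quenching, i.e. an approaching; distance changes carry the convention
## that negative values mean a shorter distance in open relative to closed
## (and desensitized relative to open). A VCF polarity is consistent with
## the structures when both point the same way and the structural change
## is at least 1 A; smaller changes are indeterminate.

parse_residue <- function(id) {
  n <- suppressWarnings(as.integer(gsub("[^0-9]", "", as.character(id))))
  if (any(is.na(n))) stop("cannot parse residue identifier: ", id)
  n
}

pair_key <- function(r1, r2) paste(as.character(r1), as.character(r2))

#' Cbeta-Cbeta distances of a residue pair in a trimer
#'
#' Euclidean distance between the beta-carbon atoms of the two residues,
#' in each of the three subunits (intrasubunit pairing) or across each of
#' the three cyclic subunit interfaces (intersubunit pairing: residue 1 of
#' each chain against residue 2 of the next chain in alphabetical order).
#'
#' @param structure a `bio3d` pdb object or the path of a PDB file.
#' @param pair length-2 vector of residue identifiers; identifiers may
#'   carry a one-letter residue-type prefix (`"S83"`), which is ignored
#'   for matching -- atoms are selected by residue number.
#' @param pairing `"intra"` (same subunit) or `"inter"` (neighboring
#'   subunit).
#' @return numeric vector of three distances (Angstrom), one per subunit
#'   or interface.
#' @export
cbeta_distances <- function(structure, pair, pairing = c("intra", "inter")) {
  pairing <- match.arg(pairing)
  if (is.character(structure)) structure <- bio3d::read.pdb(structure)
  atoms <- structure$atom
  chains <- sort(unique(atoms$chain))
  if (length(chains) != 3L)
    stop("expected a trimer with 3 chains, found ", length(chains))
  resno <- vapply(pair, parse_residue, integer(1))
  cb <- function(chain, rn) {
    i <- which(atoms$chain == chain & atoms$resno == rn &
                 atoms$elety == "CB")
    if (length(i) != 1L)
      stop(sprintf("missing Cbeta atom for residue %d in chain %s",
                   rn, chain))
    c(atoms$x[i], atoms$y[i], atoms$z[i])
  }
  partner <- if (pairing == "intra") chains else chains[c(2, 3, 1)]
  vapply(seq_along(chains), function(k) {
    sqrt(sum((cb(chains[k], resno[1]) - cb(partner[k], resno[2]))^2))
  }, numeric(1))
}

#' Distance record of a pair across the three functional states
#'
#' Distances are measured in all three subunits (or interfaces) of each
#' state structure and averaged; the average distance is the mean of the
#' three per-state means. Differences follow the convention that negative
#' values indicate a shorter distance in open relative to the closed, and
#' desensitized relative to the open conformation.
#'
#' @param structures named list with elements `closed`, `open`,
#'   `desensitized`: `bio3d` pdb objects or PDB file paths.
#' @param pair,pairing see [cbeta_distances()].
#' @return A `distance_record`: list with `residue1`, `residue2`,
#'   `avg_distance`, `delta_open_closed`, `delta_desens_open` and the
#'   per-state means `state_means`.
#' @export
state_distance_record <- function(structures, pair,
                                  pairing = c("intra", "inter")) {
  pairing <- match.arg(pairing)
  need <- c("closed", "open", "desensitized")
  if (!all(need %in% names(structures)))
    stop("'structures' must contain closed, open and desensitized")
  means <- vapply(need, function(st) {
    mean(cbeta_distances(structures[[st]], pair, pairing))
  }, numeric(1))
  distance_record(pair[1], pair[2], avg_distance = mean(means),
                  delta_open_closed = means[["open"]] - means[["closed"]],
                  delta_desens_open = means[["desensitized"]] - means[["open"]],
                  state_means = means)
}

#' Construct a distance record directly from tabulated values
#'
#' @param residue1,residue2 residue identifiers.
#' @param avg_distance mean Cbeta distance across the three states (A).
#' @param delta_open_closed,delta_desens_open distance differences (A),
#'   negative = approaching.
#' @param state_means optional named per-state means.
#' @return A `distance_record`.
#' @export
distance_record <- function(residue1, residue2, avg_distance,
                            delta_open_closed, delta_desens_open,
                            state_means = NULL) {
  if (!is.finite(avg_distance) || avg_distance <= 0)
    stop("'avg_distance' must be a positive distance")
  if (!is.finite(delta_open_closed) || !is.finite(delta_desens_open))
    stop("distance differences must be finite")
  structure(list(residue1 = residue1, residue2 = residue2,
                 avg_distance = avg_distance,
                 delta_open_closed = delta_open_closed,
                 delta_desens_open = delta_desens_open,
                 state_means = state_means),
            class = "distance_record")
}

#' Distance change of the transition a dF component is associated with
#'
#' Components associated with opening (`o`, or `< o` for movements faster
#' than opening) map to the closed-open distance change; components with
#' intermediate (`i`) or desensitization (`d`) kinetics map to the
#' open-desensitized change.
#'
#' @param record a [distance_record()].
#' @param association one of `"o"`, `"less_than_o"`, `"i"`, `"d"`.
#' @return list with `transition` (`"open_minus_closed"` or
#'   `"desens_minus_open"`) and `delta` (A).
#' @export
transition_delta <- function(record, association) {
  stopifnot(inherits(record, "distance_record"))
  if (association %in% c("o", "less_than_o")) {
    list(transition = "open_minus_closed",
         delta = record$delta_open_closed)
  } else if (association %in% c("i", "d")) {
    list(transition = "desens_minus_open",
         delta = record$delta_desens_open)
  } else {
    stop("unknown association '", association, "'")
  }
}

#' Classify a VCF annotation against the structural distance change
#'
#' A negative dF polarity predicts an approaching of the fluorophore and
#' quencher; a positive polarity a separation. The prediction is
#' `consistent` when the structural distance change of the associated
#' transition points the same way with magnitude of at least `threshold`,
#' `contradicts` when it points the opposite way with at least that
#' magnitude, and `indeterminate` when the structural change is smaller
#' than `threshold` (too small to interpret). Pairs flagged excluded
#' (distance above 20 A, or a non-desensitizing mutant) are labelled
#' `excluded` unless `apply_exclusion = FALSE`.
#'
#' @param annotation one annotation: a list or one-row data frame with
#'   fields `residue1`, `residue2`, `polarity` (`"neg"`/`"pos"`),
#'   `association`, `excluded`.
#' @param record the [distance_record()] of the same pair.
#' @param threshold minimum interpretable distance change (A).
#' @param apply_exclusion honour the `excluded` flag (default `TRUE`).
#' @return A `concordance_label`: list with `label`, `transition_used`,
#'   `delta_used`.
#' @export
classify_pair <- function(annotation, record, threshold = 1.0,
                          apply_exclusion = TRUE) {
  annotation <- as.list(annotation)
  if (parse_residue(annotation$residue1) != parse_residue(record$residue1) ||
      parse_residue(annotation$residue2) != parse_residue(record$residue2))
    stop("annotation and distance record refer to different pairs")
  td <- transition_delta(record, annotation$association)
  if (apply_exclusion && isTRUE(as.logical(annotation$excluded))) {
    label <- "excluded"
  } else if (abs(td$delta) < threshold) {
    label <- "indeterminate"
  } else {
    approaching <- td$delta <= -threshold
    label <- if (identical(annotation$polarity, "neg") == approaching)
      "consistent" else "contradicts"
  }
  structure(list(label = label, transition_used = td$transition,
                 delta_used = td$delta),
            class = "concordance_label")
}

#' Read the packaged VCF annotation table
#'
#' One row per dF signal component: residue pair, component
#' (single/first/second), polarity, kinetic association, intersubunit
#' flag, exclusion flag and reason, and the classification printed in the
#' source table (`printed_font`: bold = consistent, italics = contradicts,
#' regular = indeterminate).
#'
#' @param path CSV file; defaults to the packaged transcription.
#' @return data frame of annotations.
#' @export
read_table1 <- function(path = system.file("extdata", "table1.csv",
                                           package = "asicvcf")) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("residue1", "residue2", "component", "polarity", "association",
            "intersubunit", "excluded", "exclusion_reason")
  if (!all(need %in% names(df)))
    stop("annotation table misses columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  df$intersubunit <- as.logical(df$intersubunit)
  df$excluded <- as.logical(df$excluded)
  df
}

#' Read the packaged Cbeta distance table
#'
#' @param path CSV file; defaults to the packaged transcription.
#' @return data frame with columns `residue1`, `residue2`,
#'   `avg_distance_A`, `delta_open_closed_A`, `delta_desens_open_A`.
#' @export
read_table2 <- function(path = system.file("extdata", "table2.csv",
                                           package = "asicvcf")) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("residue1", "residue2", "avg_distance_A", "delta_open_closed_A",
            "delta_desens_open_A")
  if (!all(need %in% names(df)))
    stop("distance table misses columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  df
}

records_from_table <- function(table2) {
  recs <- lapply(seq_len(nrow(table2)), function(i) {
    distance_record(table2$residue1[i], table2$residue2[i],
                    table2$avg_distance_A[i], table2$delta_open_closed_A[i],
                    table2$delta_desens_open_A[i])
  })
  names(recs) <- pair_key(table2$residue1, table2$residue2)
  recs
}

#' Re-derive exclusions from the distance table and mutant behaviour
#'
#' A pair is excluded from structural interpretation when its average
#' Cbeta distance exceeds `distance_threshold` (too far for quenching) or
#' when the mutant carrying the quencher did not desensitize (flagged in
#' the annotations).
#'
#' @param annotations a [read_table1()] data frame.
#' @param records a [read_table2()] data frame.
#' @param distance_threshold exclusion distance (A), default 20.
#' @return the annotations with recomputed `excluded` and
#'   `exclusion_reason` columns.
#' @export
apply_exclusions <- function(annotations, records, distance_threshold = 20) {
  recs <- records_from_table(records)
  key <- pair_key(annotations$residue1, annotations$residue2)
  avg <- vapply(key, function(k) {
    if (is.null(recs[[k]])) NA_real_ else recs[[k]]$avg_distance
  }, numeric(1))
  non_des <- annotations$exclusion_reason == "non_desensitizing"
  far <- !is.na(avg) & avg > distance_threshold
  annotations$excluded <- far | non_des
  annotations$exclusion_reason <- ifelse(far, "distance_gt_20A",
                                         ifelse(non_des, "non_desensitizing",
                                                "none"))
  annotations
}

#' Classify every annotated pair and compare with the printed labels
#'
#' @param annotations a [read_table1()] data frame.
#' @param records a [read_table2()] data frame.
#' @param threshold interpretation threshold (A).
#' @return the annotations extended with `label`, `transition_used`,
#'   `delta_used` and (when `printed_font` is present) `printed_label` and
#'   `font_match`.
#' @export
concordance_table <- function(annotations, records, threshold = 1.0) {
  recs <- records_from_table(records)
  out <- annotations
  cls <- lapply(seq_len(nrow(out)), function(i) {
    k <- pair_key(out$residue1[i], out$residue2[i])
    if (is.null(recs[[k]]))
      stop("no distance record for pair ", k)
    classify_pair(out[i, ], recs[[k]], threshold = threshold,
                  apply_exclusion = FALSE)
  })
  out$label <- vapply(cls, `[[`, character(1), "label")
  out$transition_used <- vapply(cls, `[[`, character(1), "transition_used")
  out$delta_used <- vapply(cls, `[[`, numeric(1), "delta_used")
  if ("printed_font" %in% names(out)) {
    out$printed_label <- c(bold = "consistent", italic = "contradicts",
                           regular = "indeterminate")[out$printed_font]
    out$font_match <- out$label == out$printed_label
  }
  out
}

#' Summary counts of the VCF / structure concordance analysis
#'
#' Counts annotations per transition (closed-open vs open-desensitized),
#' the intra/intersubunit split, exclusions and the retained sets, the
#' classification labels among retained pairs (when distance records are
#' supplied), and the quencher-location subsets: the beta5-beta6 loop of
#' the beta-ball (quencher positions 205-210) and the palm-thumb /
#' neighboring-subunit set (positions 289, 357, 358, 359, 369).
#'
#' @param annotations a [read_table1()] data frame.
#' @param records optionally a [read_table2()] data frame; without it only
#'   the count-based summaries are produced.
#' @param threshold interpretation threshold (A).
#' @return An object of class `concordance_summary` (a list of counts).
#' @export
summarize_table <- function(annotations, records = NULL, threshold = 1.0) {
  key <- paste(pair_key(annotations$residue1, annotations$residue2),
               annotations$component)
  if (anyDuplicated(key))
    stop("duplicate pair+component entries: ",
         paste(key[duplicated(key)], collapse = ", "))
  co <- annotations$association %in% c("o", "less_than_o")
  od <- annotations$association %in% c("i", "d")
  q <- vapply(annotations$residue2, parse_residue, integer(1))
  loop <- q %in% 205:210
  palm_thumb <- q %in% c(289, 357, 358, 359, 369)
  out <- list(
    n_pairs = nrow(annotations),
    closed_open = sum(co),
    closed_open_intrasubunit = sum(co & !annotations$intersubunit),
    closed_open_intersubunit = sum(co & annotations$intersubunit),
    open_desens = sum(od),
    excluded = sum(annotations$excluded),
    open_desens_retained = sum(od & !annotations$excluded),
    loop_205_210 = sum(loop),
    loop_205_210_opening = sum(loop & co),
    loop_205_210_desens = sum(loop & od),
    palm_thumb_closed_open = sum(palm_thumb & co),
    palm_thumb_open_desens = sum(palm_thumb & od))
  if (!is.null(records)) {
    ct <- concordance_table(annotations, records, threshold = threshold)
    keep <- !ct$excluded
    for (tr in c("closed_open", "open_desens")) {
      sel <- keep & if (tr == "closed_open") co else od
      for (lab in c("consistent", "contradicts", "indeterminate")) {
        out[[paste(tr, lab, sep = "_")]] <- sum(ct$label[sel] == lab)
      }
    }
  }
  structure(out, class = "concordance_summary")
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat("VCF / structure concordance summary\n")
  cat(sprintf("  closed-open changes: %d (%d intra-, %d intersubunit)\n",
              x$closed_open, x$closed_open_intrasubunit,
              x$closed_open_intersubunit))
  cat(sprintf("  open-desensitized changes: %d (%d retained, %d excluded overall)\n",
              x$open_desens, x$open_desens_retained, x$excluded))
  if (!is.null(x$open_desens_contradicts))
    cat(sprintf("  retained open-desensitized: %d consistent, %d contradicting, %d indeterminate\n",
                x$open_desens_consistent, x$open_desens_contradicts,
                x$open_desens_indeterminate))
  invisible(x)
}
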