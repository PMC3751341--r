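#' Construct a miRNA hairpin reference
#'
#' A reference couples a precursor hairpin sequence with the coordinates of
#' its annotated mature miRNA(s). Coordinates are 0-based half-open on the
#' hairpin; the hairpin substring `[start, end)` is the annotated mature
#' sequence.
#'
#' @param hairpin_id hairpin name.
#' @param hairpin_seq hairpin (precursor) sequence.
#' @param matures a `data.frame` with columns `mature_name`, `start`, `end`
#'   (0-based half-open on the hairpin).
#' @return an object of class `mirna_reference`.
#' @export
mirna_reference <- function(hairpin_id, hairpin_seq, matures) {
  hairpin_seq <- normalize_rna(hairpin_seq)
  stopifnot(is.data.frame(matures),
            all(c("mature_name", "start", "end") %in% names(matures)))
  n <- nchar(hairpin_seq)
  for (i in seq_len(nrow(matures))) {
    s <- matures$start[i]; e <- matures$end[i]
    if (!(s >= 0 && s < e && e <= n)) {
      stop(sprintf("mature '%s': invalid coordinates [%d, %d) on %d-nt hairpin",
                   matures$mature_name[i], s, e, n))
    }
    if (e - s < 16) {
      stop(sprintf("mature '%s': length %d < 16", matures$mature_name[i], e - s))
    }
  }
  structure(list(hairpin_id = hairpin_id,
                 hairpin_seq = hairpin_seq,
                 matures = matures[, c("mature_name", "start", "end")]),
            class = "mirna_reference")
}

#' @export
print.mirna_reference <- function(x, ...) {
  cat(sprintf("<mirna_reference> %s (%d nt), %d mature(s): %s\n",
              x$hairpin_id, nchar(x$hairpin_seq), nrow(x$matures),
              paste(x$matures$mature_name, collapse = ", ")))
  invisible(x)
}

#' Mature sequence annotated on a reference
#'
#' @param reference a `mirna_reference`.
#' @param mature_name which annotated mature; default the first.
#' @return the mature sequence (character scalar).
#' @export
mature_sequence <- function(reference, mature_name = NULL) {
  m <- reference$matures
  if (!is.null(mature_name)) m <- m[m$mature_name == mature_name, , drop = FALSE]
  if (nrow(m) == 0) stop("mature not found on reference")
  substr(reference$hairpin_seq, m$start[1] + 1, m$end[1])
}

#' Read mature-on-hairpin annotations (sidecar TSV)
#'
#' The sidecar table has columns `hairpin_id`, `mature_name`, `start`,
#' `end` with 0-based half-open coordinates on the hairpin.
#'
#' @param fasta_path hairpin FASTA.
#' @param sidecar_path annotation TSV.
#' @return a list of `mirna_reference` objects.
#' @export
read_mirna_references <- function(fasta_path, sidecar_path) {
  fa <- read_fasta(fasta_path)
  ann <- utils::read.delim(sidecar_path, stringsAsFactors = FALSE)
  need <- c("hairpin_id", "mature_name", "start", "end")
  if (!all(need %in% names(ann))) {
    stop(sprintf("%s: expected columns %s", sidecar_path,
                 paste(need, collapse = ", ")))
  }
  missing_hp <- setdiff(unique(ann$hairpin_id), fa$id)
  if (length(missing_hp) > 0) {
    stop(sprintf("annotation references unknown hairpin '%s'", missing_hp[1]))
  }
  lapply(split(ann, ann$hairpin_id)[unique(ann$hairpin_id)], function(a) {
    mirna_reference(a$hairpin_id[1],
                    fa$sequence[match(a$hairpin_id[1], fa$id)],
                    a[, c("mature_name", "start", "end")])
  })
}

#' Write the reference sidecar TSV
#'
#' @param references list of `mirna_reference` objects.
#' @param fasta_path,sidecar_path output paths.
#' @return `sidecar_path`, invisibly.
#' @export
write_mirna_references <- function(references, fasta_path, sidecar_path) {
  write_fasta(vapply(references, `[[`, "", "hairpin_id"),
              vapply(references, `[[`, "", "hairpin_seq"),
              fasta_path)
  ann <- do.call(rbind, lapply(references, function(r) {
    cbind(hairpin_id = r$hairpin_id, r$matures)
  }))
  utils::write.table(ann, sidecar_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(sidecar_path)
}

# Enumerate all decompositions of `sequence` against one reference and
# return the best one, or NULL. The objective prefers templated
# explanations: fewest substitutions, then fewest non-templated additions,
# then smallest total end shift |t5| + |t3|; remaining ties are broken on
# (t5, t3) for determinism. `t5` is the read 5' start minus the mature
# start (negative = upstream extension); `t3` is the templated 3' end
# minus the mature end (negative = trimmed). Additions come out as the
# maximal non-templated suffix because any added base that matches the
# hairpin base it would occupy yields a competing decomposition with
# fewer additions and equal substitutions, which the objective prefers.
best_decomposition <- function(sequence, reference, max_trim, max_add, max_sub) {
  L <- nchar(sequence)
  rc <- seq_chars(sequence)
  hp <- seq_chars(reference$hairpin_seq)
  n_hp <- length(hp)
  best <- NULL
  best_key <- NULL
  for (i in seq_len(nrow(reference$matures))) {
    s0 <- reference$matures$start[i]
    e0 <- reference$matures$end[i]
    mname <- reference$matures$mature_name[i]
    for (t5 in -max_trim:max_trim) {
      start <- s0 + t5
      if (start < 0) next
      for (n_add in 0:max_add) {
        tlen <- L - n_add
        if (tlen < 1) next
        tend <- start + tlen
        if (tend > n_hp) next
        t3 <- tend - e0
        if (abs(t3) > max_trim) next
        mism <- which(rc[seq_len(tlen)] != hp[(start + 1):tend])
        if (length(mism) > max_sub) next
        key <- c(length(mism), n_add, abs(t5) + abs(t3), t5, t3)
        if (is.null(best_key) ||
            isTRUE(vec_less(key, best_key))) {
          best_key <- key
          best <- list(mature_name = mname, t5 = t5, t3 = t3,
                       additions = if (n_add > 0) substr(sequence, tlen + 1, L) else "",
                       sub_pos = mism - 1L,            # 0-based on the read
                       sub_ref = hp[start + mism],
                       sub_read = rc[mism],
                       objective = key)
        }
      }
    }
  }
  best
}

# lexicographic strictly-less on numeric vectors of equal length
vec_less <- function(a, b) {
  d <- a - b
  nz <- which(d != 0)
  length(nz) > 0 && d[nz[1]] < 0
}

#' Assign a read to a mature miRNA locus on a hairpin
#'
#' Searches all decompositions of the read as (5' shift `t5`, templated 3'
#' shift `t3`, non-templated 3' additions, internal substitutions) against
#' the annotated mature(s) of one hairpin, within the variant bounds, and
#' returns the decomposition minimizing `(substitutions, additions,
#' |t5| + |t3|)` lexicographically. Additions are exactly the maximal
#' non-templated suffix: each added base is compared against the hairpin
#' base it would occupy, and templated explanations win. A read that
#' admits no decomposition within bounds (including one that would extend
#' beyond the hairpin) is unassigned (`NULL`), not an error.
#'
#' Sign convention: `t5 < 0` means the read starts upstream of the mature
#' 5' end (the seed register shifts); `t3 < 0` means the templated 3' end
#' is trimmed relative to the mature.
#'
#' @param sequence read sequence.
#' @param reference a `mirna_reference`.
#' @param max_trim maximum `|t5|` and `|t3|` (default 3).
#' @param max_add maximum number of non-templated 3' additions (default 3).
#' @param max_sub maximum substitutions (default 1).
#' @return an `isomir_call` (list with fields `sequence`, `hairpin_id`,
#'   `mature_name`, `t5`, `t3`, `additions`, `substitutions` (data frame
#'   with 0-based `position`, `ref_base`, `read_base`), `seed7`), or
#'   `NULL` when unassigned.
#' @export
map_read_to_hairpin <- function(sequence, reference, max_trim = 3,
                                max_add = 3, max_sub = 1) {
  sequence <- normalize_rna(sequence, allow_n = FALSE)
  d <- best_decomposition(sequence, reference, max_trim, max_add, max_sub)
  if (is.null(d)) return(NULL)
  structure(list(
    sequence = sequence,
    hairpin_id = reference$hairpin_id,
    mature_name = d$mature_name,
    t5 = d$t5, t3 = d$t3,
    additions = d$additions,
    substitutions = data.frame(position = d$sub_pos,
                               ref_base = as.character(d$sub_ref),
                               read_base = as.character(d$sub_read),
                               stringsAsFactors = FALSE),
    seed7 = if (nchar(sequence) >= 8) substr(sequence, 2, 8) else NA_character_,
    objective = d$objective
  ), class = "isomir_call")
}

#' Classify an isomiR call into variant labels
#'
#' Labels are a subset of `{reference, trim5, trim3, add3, substitution}`:
#' `reference` iff the read matches the annotated mature exactly
#' (`t5 = t3 = 0`, no additions, no substitutions); otherwise `trim5` for
#' any 5' end shift, `trim3` for any templated 3' end shift, `add3` for
#' non-templated 3' additions, `substitution` for internal mismatches.
#' Labels combine (e.g. `trim5+trim3`).
#'
#' @param call an `isomir_call`, or a data frame row with fields `t5`,
#'   `t3`, `additions`, `n_substitutions`.
#' @return character vector of labels.
#' @export
classify_variant <- function(call) {
  if (inherits(call, "isomir_call")) {
    t5 <- call$t5; t3 <- call$t3
    n_add <- nchar(call$additions)
    n_sub <- nrow(call$substitutions)
  } else {
    t5 <- call$t5; t3 <- call$t3
    n_add <- nchar(call$additions)
    n_sub <- call$n_substitutions
  }
  labels <- c(if (t5 != 0) "trim5",
              if (t3 != 0) "trim3",
              if (n_add > 0) "add3",
              if (n_sub > 0) "substitution")
  if (is.null(labels)) "reference" else labels
}

# canonical composite label, e.g. "trim5+trim3"
variant_label_string <- function(labels) paste(labels, collapse = "+")

# encode substitutions as "pos:REF>READ" (0-based read position), ";"-joined
encode_substitutions <- function(subs) {
  if (nrow(subs) == 0) return("")
  paste(sprintf("%d:%s>%s", subs$position, subs$ref_base, subs$read_base),
        collapse = ";")
}

#' Call isomiRs for one sample
#'
#' Assigns each collapsed read to at most one (hairpin, mature) locus.
#' When several references admit a decomposition, the best one under the
#' [map_read_to_hairpin()] objective wins; remaining ties are broken by
#' lexicographic `mature_name` so calls are deterministic and independent
#' of read or reference order. Counts are carried through unchanged.
#'
#' @param reads a `data.frame` with columns `sequence`, `count`.
#' @param references non-empty list of `mirna_reference` objects.
#' @param max_trim,max_add,max_sub variant bounds (defaults 3, 3, 1).
#' @return a list with `calls` (data frame: `sequence`, `count`, `length`,
#'   `hairpin_id`, `mature_name`, `t5`, `t3`, `additions`,
#'   `substitutions`, `n_substitutions`, `seed7`, `variant_labels`) and
#'   `unassigned` (the reads with no decomposition within bounds).
#' @export
call_sample <- function(reads, references, max_trim = 3, max_add = 3,
                        max_sub = 1) {
  if (length(references) == 0) stop("references must be non-empty")
  stopifnot(is.data.frame(reads), all(c("sequence", "count") %in% names(reads)))
  rows <- vector("list", nrow(reads))
  unassigned <- logical(nrow(reads))
  for (i in seq_len(nrow(reads))) {
    calls <- lapply(references, function(ref) {
      map_read_to_hairpin(reads$sequence[i], ref, max_trim, max_add, max_sub)
    })
    calls <- calls[!vapply(calls, is.null, TRUE)]
    if (length(calls) == 0) {
      unassigned[i] <- TRUE
      next
    }
    keys <- lapply(calls, `[[`, "objective")
    names_ <- vapply(calls, `[[`, "", "mature_name")
    best <- 1L
    for (j in seq_along(calls)[-1]) {
      if (vec_less(keys[[j]], keys[[best]]) ||
          (identical(keys[[j]], keys[[best]]) && names_[j] < names_[best])) {
        best <- j
      }
    }
    cl <- calls[[best]]
    rows[[i]] <- data.frame(
      sequence = cl$sequence,
      count = reads$count[i],
      length = nchar(cl$sequence),
      hairpin_id = cl$hairpin_id,
      mature_name = cl$mature_name,
      t5 = cl$t5, t3 = cl$t3,
      additions = cl$additions,
      substitutions = encode_substitutions(cl$substitutions),
      n_substitutions = nrow(cl$substitutions),
      seed7 = cl$seed7,
      variant_labels = variant_label_string(classify_variant(cl)),
      stringsAsFactors = FALSE)
  }
  calls_df <- do.call(rbind, rows[!unassigned])
  if (is.null(calls_df)) {
    calls_df <- data.frame(sequence = character(), count = integer(),
                           length = integer(), hairpin_id = character(),
                           mature_name = character(), t5 = integer(),
                           t3 = integer(), additions = character(),
                           substitutions = character(),
                           n_substitutions = integer(), seed7 = character(),
                           variant_labels = character(),
                           stringsAsFactors = FALSE)
  }
  rownames(calls_df) <- NULL
  list(calls = calls_df,
       unassigned = reads[unassigned, , drop = FALSE])
}

#' Reconstruct a read from its isomiR decomposition
#'
#' Applies `(t5, t3, substitutions, additions)` to the hairpin; the result
#' must equal the called read exactly (used as a round-trip invariant).
#'
#' @param call an `isomir_call` or one row of a `call_sample()` table.
#' @param reference the `mirna_reference` the call was made against.
#' @return the reconstructed read sequence.
#' @export
reconstruct_read <- function(call, reference) {
  m <- reference$matures[reference$matures$mature_name == call$mature_name, ]
  if (nrow(m) == 0) stop("call does not belong to this reference")
  start <- m$start[1] + call$t5
  end <- m$end[1] + call$t3
  core <- seq_chars(substr(reference$hairpin_seq, start + 1, end))
  if (inherits(call, "isomir_call")) {
    subs <- call$substitutions
  } else if (nzchar(call$substitutions)) {
    parts <- strsplit(strsplit(call$substitutions, ";", fixed = TRUE)[[1]],
                      "[:>]")
    subs <- data.frame(position = as.integer(vapply(parts, `[[`, "", 1)),
                       ref_base = vapply(parts, `[[`, "", 2),
                       read_base = vapply(parts, `[[`, "", 3))
  } else {
    subs <- data.frame(position = integer(), ref_base = character(),
                       read_base = character())
  }
  if (nrow(subs) > 0) core[subs$position + 1L] <- subs$read_base
  paste0(paste(core, collapse = ""), call$additions)
}

#' Write / read the per-sample isomiR table (TSV)
#'
#' Columns: `sequence`, `count`, `length`, `hairpin_id`, `mature_name`,
#' `t5`, `t3`, `additions`, `substitutions`, `n_substitutions`, `seed7`,
#' `variant_labels`.
#'
#' @param calls the `calls` data frame from [call_sample()].
#' @param path file path.
#' @return the path (writer) or the table (reader).
#' @export
write_isomir_table <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_isomir_table
#' @export
read_isomir_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(additions = "character",
                                         substitutions = "character"))
  df$additions[is.na(df$additions)] <- ""
  df$substitutions[is.na(df$substitutions)] <- ""
  df
}
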