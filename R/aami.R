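#' The five AAMI heartbeat classes
#'
#' Class order is fixed as N, S, V, F, Q everywhere in the package (confusion
#' matrices, probability columns, ROC class indices 0-4).
#'
#' @return Character vector `c("N", "S", "V", "F", "Q")`.
#' @export
aami_classes <- function() c("N", "S", "V", "F", "Q")

# MIT-BIH beat annotation symbol -> AAMI class, following the AAMI EC57
# grouping: N collects normal, bundle-branch-block and escape beats; S the
# supraventricular ectopics; V the ventricular ectopics; F ventricular fusion;
# Q paced, paced-fusion and unclassifiable beats.
.aami_symbol_map <- c(
  "N" = "N", "L" = "N", "R" = "N", "e" = "N", "j" = "N",
  "A" = "S", "a" = "S", "J" = "S", "S" = "S",
  "V" = "V", "E" = "V",
  "F" = "F",
  "/" = "Q", "f" = "Q", "Q" = "Q"
)

#' Map beat annotation symbols to AAMI classes
#'
#' Translates MIT-BIH single-character beat annotation symbols (e.g. `"L"`
#' left bundle branch block, `"A"` atrial premature, `"/"` paced) to the
#' five-class AAMI scheme. The mapping is case-sensitive and total on the
#' standard beat symbol set.
#'
#' @param symbol Character vector of single-character beat symbols.
#' @param lenient If `TRUE`, symbols outside the known set map to `"Q"`
#'   (unclassified); if `FALSE` (default) they raise an error.
#' @return Character vector of AAMI classes, same length as `symbol`.
#' @examples
#' map_symbol_to_aami(c("N", "L", "A", "V", "/"))
#' @export
map_symbol_to_aami <- function(symbol, lenient = FALSE) {
  stopifnot(is.character(symbol))
  out <- unname(.aami_symbol_map[symbol])
  if (anyNA(out)) {
    if (lenient) {
      out[is.na(out)] <- "Q"
    } else {
      bad <- unique(symbol[is.na(out)])
      abort(paste0("unknown beat annotation symbol(s): ",
                   paste(sQuote(bad), collapse = ", "),
                   " (use lenient = TRUE to map them to Q)"))
    }
  }
  out
}

#' Beat annotation symbols recognised as heartbeats
#'
#' Non-beat annotation symbols (rhythm changes `"+"`, noise `"~"`, signal
#' quality marks, etc.) are dropped before any counting or segmentation.
#'
#' @return Character vector of the known beat symbols.
#' @export
beat_symbols <- function() names(.aami_symbol_map)

#' Count beats per AAMI class
#'
#' Tallies the mapped beat annotations of one or more ECG records. Non-beat
#' annotation symbols are ignored; the per-class counts therefore sum to the
#' number of retained beat annotations.
#'
#' @param records A single `ecg_record` or a list of them.
#' @param lenient Passed to [map_symbol_to_aami()].
#' @return A tibble with columns `class` (factor over N,S,V,F,Q) and `n`;
#'   always five rows, zero counts included.
#' @export
count_classes <- function(records, lenient = FALSE) {
  if (inherits(records, "ecg_record")) records <- list(records)
  syms <- unlist(lapply(records, function(r) r$annotations$symbol),
                 use.names = FALSE)
  syms <- syms[syms %in% beat_symbols() |
                 (lenient & !syms %in% beat_symbols())]
  cls <- if (length(syms)) map_symbol_to_aami(syms, lenient = lenient) else character(0)
  tab <- table(factor(cls, levels = aami_classes()))
  tibble(class = factor(aami_classes(), levels = aami_classes()),
         n = as.integer(tab))
}

#' Standard augmentation targets for the five AAMI classes
#'
#' Per-class beat counts targeted after GAN augmentation of the MIT-BIH
#' arrhythmia database: the majority class N is left at its raw count and the
#' four minority classes are expanded to roughly 20k beats each
#' (total 171,742).
#'
#' @return Named integer vector over N, S, V, F, Q.
#' @export
aami_augment_targets <- function() {
  c(N = 90589L, S = 20179L, V = 20236L, F = 20339L, Q = 20399L)
}

#' Raw MIT-BIH per-class beat counts
#'
#' Reference per-class beat totals of the MIT-BIH arrhythmia database under
#' the AAMI mapping (109,446 beats). Useful for planning augmentation without
#' the database on disk.
#'
#' @return Named integer vector over N, S, V, F, Q.
#' @export
mitdb_class_counts <- function() {
  c(N = 90589L, S = 2779L, V = 7236L, F = 803L, Q = 8039L)
}

#' Plan a class-balancing augmentation
#'
#' Computes, per class, how many synthetic beats are needed to lift given raw
#' counts to given targets. Pure count arithmetic; [augment_beats()] executes
#' the plan on an actual beat table.
#'
#' @param counts Named numeric vector (or tibble from [count_classes()]) of
#'   raw per-class counts.
#' @param targets Named numeric vector of target counts; defaults to
#'   [aami_augment_targets()].
#' @return Tibble with columns `class`, `n_real`, `target`, `n_generated`.
#' @export
augment_plan <- function(counts, targets = aami_augment_targets()) {
  if (is.data.frame(counts)) {
    counts <- stats::setNames(counts$n, as.character(counts$class))
  }
  cls <- aami_classes()
  counts <- counts[cls]
  targets <- targets[cls]
  if (anyNA(counts) || anyNA(targets)) {
    abort("counts and targets must cover all five AAMI classes")
  }
  if (any(targets < counts)) {
    abort("augmentation target below the raw count for class(es): ",
          paste(cls[targets < counts], collapse = ", "))
  }
  tibble(class = factor(cls, levels = cls),
         n_real = as.integer(counts),
         target = as.integer(targets),
         n_generated = as.integer(targets - counts))
}
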