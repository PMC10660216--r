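#' Pool amino-acid composition across proteins
#'
#' Residue counts are pooled over all proteins (equivalent to
#' length-weighted averaging, not a per-protein mean of fractions), which
#' matches defining F_IVYWREL over the whole proteome of a sample.  Only
#' the 20 standard residues are counted; `X`, `*`, `B`, `Z`, `U` and gap
#' characters enter neither numerator nor denominator, so no residue is
#' fabricated from ambiguous sequence.
#'
#' @param proteins Character vector of protein strings, an ORF tibble from
#'   [find_orfs()] (its `protein` column is used), or a protein tibble from
#'   [read_proteins()] (its `seq` column).
#' @return An `aa_composition` object: residue counts, `total` counted
#'   residues and `f_ivywrel`, the pooled fraction of Ile, Val, Tyr, Trp,
#'   Arg, Glu and Leu (`NA` when `total` is 0).
#' @examples
#' pool_composition(c("IV", "GGGGGG"))$f_ivywrel # 2/8, pooled
#' @export
pool_composition <- function(proteins) {
  if (is.data.frame(proteins)) {
    proteins <- if ("protein" %in% names(proteins)) {
      proteins$protein
    } else {
      proteins$seq
    }
  }
  chars <- unlist(strsplit(toupper(proteins), "", fixed = TRUE), use.names = FALSE)
  counts <- table(factor(chars, levels = STANDARD_AA))
  counts <- setNames(as.integer(counts), STANDARD_AA)
  total <- sum(counts)
  structure(
    list(
      counts = counts,
      total = total,
      f_ivywrel = if (total > 0) sum(counts[IVYWREL]) / total else NA_real_
    ),
    class = "aa_composition"
  )
}

#' @export
print.aa_composition <- function(x, ...) {
  cat("Pooled amino-acid composition\n")
  cat("  residues counted:", x$total, "\n")
  cat(
    "  F_IVYWREL:",
    if (is.na(x$f_ivywrel)) "undefined (no residues)" else sprintf("%.5f", x$f_ivywrel),
    "\n"
  )
  invisible(x)
}

#' @describeIn pool_composition Per-residue counts and frequencies as a
#'   tibble, flagging the seven thermal-signal residues.
#' @param x An `aa_composition` object.
#' @param ... Unused.
#' @export
tidy.aa_composition <- function(x, ...) {
  tibble(
    residue = names(x$counts),
    count = unname(x$counts),
    frequency = if (x$total > 0) unname(x$counts) / x$total else NA_real_,
    ivywrel = names(x$counts) %in% IVYWREL
  )
}

#' Convert an IVYWREL fraction to a predicted temperature
#'
#' The linear calibration between prokaryotic optimal growth temperature
#' and the proteome fraction of Ile, Val, Tyr, Trp, Arg, Glu and Leu:
#' \deqn{T = 937 f_{IVYWREL} - 335}
#' in degrees Celsius.  Applied to a single genome the result is a
#' predicted optimal growth temperature (OGT); applied to the pooled
#' coding fraction of a metagenome it is the metagenomic predicted
#' temperature (MPT).  The value is returned unclamped: the calibration is
#' linear and masking extrapolation would hide QC problems.
#'
#' @param f Numeric vector of IVYWREL fractions in \[0, 1\].
#' @return Predicted temperature(s) in degrees Celsius.
#' @examples
#' mpt_from_f(c(0, 0.5, 1)) # -335, 133.5, 602
#' @export
mpt_from_f <- function(f) {
  if (!is.numeric(f) || anyNA(f) || any(f < 0 | f > 1)) {
    abort("`f` must be numeric in [0, 1]")
  }
  937 * f - 335
}

#' Predict the temperature of an environment from metagenomic reads
#'
#' The full metagenomic-thermometer pipeline: read quality filtering
#' (length and ambiguous-base limits), optional identifier-based read
#' exclusion, six-frame ORF extraction, per-read coding-frame resolution,
#' composition pooling and the linear temperature calibration (see
#' [mpt_from_f()]).
#'
#' A sample whose reads yield no ORF at all carries no coding signal; the
#' report then has status `"insufficient coding signal"` and an `NA`
#' temperature rather than a fabricated number.  Predictions outside the
#' 0--100 degree calibration regime are reported as-is with a warning.
#'
#' @param reads A reads tibble (see [read_sequences()]) or a path to a
#'   FASTA/FASTQ file.
#' @param min_len,max_n Quality-filter limits, see [quality_filter()].
#' @param min_aa,mode,starts ORF-caller parameters, see [find_orfs()].
#' @param orf_selection Per-read frame-resolution policy passed to
#'   [select_orfs()]; default `"likelihood"`.
#' @param exclude_ids Optional character vector (or id-list file path) of
#'   read identifiers to drop before prediction.
#' @param sample Optional sample label carried into the report.
#' @return A `thermo_report` object; see [tidy.thermo_report()] and
#'   [glance.thermo_report()].
#' @examples
#' reads <- tibble::tibble(
#'   id = "r1",
#'   seq = paste0("ATG", strrep("ATTGTT", 30), "TAA"),
#'   qual = NA_character_
#' )
#' predict_mpt(reads)
#' @export
predict_mpt <- function(reads, min_len = 50, max_n = 1, min_aa = 20,
                        mode = c("fragment", "complete"),
                        starts = DEFAULT_STARTS,
                        orf_selection = c("likelihood", "longest", "all"),
                        exclude_ids = NULL, sample = NULL) {
  mode <- match.arg(mode)
  orf_selection <- match.arg(orf_selection)
  if (is.character(reads) && length(reads) == 1 && file.exists(reads)) {
    if (is.null(sample)) {
      sample <- sub("\\.(gz)$", "", basename(reads))
    }
    reads <- read_sequences(reads)
  }
  sample <- sample %||% "sample"
  if (!is.null(exclude_ids)) {
    if (length(exclude_ids) == 1 && file.exists(exclude_ids)) {
      exclude_ids <- read_id_list(exclude_ids)
    }
    reads <- exclude_by_id(reads, exclude_ids)
  }
  passed <- quality_filter(reads, min_len = min_len, max_n = max_n)
  st <- filter_stats(passed)
  orfs <- find_orfs(passed, min_aa = min_aa, mode = mode, starts = starts)
  used <- select_orfs(orfs, method = orf_selection)
  comp <- pool_composition(used)
  mpt <- if (comp$total > 0) mpt_from_f(comp$f_ivywrel) else NA_real_
  status <- if (comp$total > 0) "ok" else "insufficient coding signal"
  if (!is.na(mpt) && (mpt < 0 || mpt > 100)) {
    warn(sprintf(
      "MPT %.2f °C is outside the 0-100 °C calibration regime", mpt
    ))
  }
  structure(
    list(
      sample = sample,
      n_reads_in = st$n_in,
      n_reads_pass = st$n_pass,
      n_fail_len = st$n_fail_len,
      n_fail_n = st$n_fail_n,
      n_orfs = nrow(orfs),
      n_orfs_used = nrow(used),
      n_residues = comp$total,
      composition = comp,
      f_ivywrel = comp$f_ivywrel,
      mpt_celsius = mpt,
      status = status,
      params = list(
        min_len = min_len, max_n = max_n, min_aa = min_aa, mode = mode,
        starts = starts, orf_selection = orf_selection
      )
    ),
    class = "thermo_report"
  )
}

#' @export
print.thermo_report <- function(x, ...) {
  cat("Metagenomic thermometer report --", x$sample, "\n")
  cat(sprintf(
    "  reads: %d in, %d passed QC (%d short, %d too many N)\n",
    x$n_reads_in, x$n_reads_pass, x$n_fail_len, x$n_fail_n
  ))
  cat(sprintf(
    "  ORFs: %d called, %d used; residues counted: %d\n",
    x$n_orfs, x$n_orfs_used, x$n_residues
  ))
  if (x$status == "ok") {
    cat(sprintf("  F_IVYWREL: %.5f\n", x$f_ivywrel))
    cat(sprintf("  MPT: %.2f °C\n", x$mpt_celsius))
  } else {
    cat("  status:", x$status, "\n")
  }
  invisible(x)
}

#' Tidy and summary views of a thermometer report
#'
#' `tidy()` returns the per-residue pooled composition; `glance()` returns
#' the one-row sample summary used for machine output.
#'
#' @param x A `thermo_report` from [predict_mpt()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.thermo_report <- function(x, ...) {
  tidy(x$composition)
}

#' @rdname tidy.thermo_report
#' @export
glance.thermo_report <- function(x, ...) {
  tibble(
    sample = x$sample,
    n_reads_in = x$n_reads_in,
    n_reads_pass = x$n_reads_pass,
    n_orfs = x$n_orfs,
    n_orfs_used = x$n_orfs_used,
    n_residues = x$n_residues,
    f_ivywrel = x$f_ivywrel,
    mpt_celsius = x$mpt_celsius,
    status = x$status
  )
}

#' Plot the pooled composition behind a temperature prediction
#'
#' Bar chart of pooled residue frequencies with the seven thermal-signal
#' residues highlighted; the subtitle restates F_IVYWREL and the predicted
#' temperature.
#'
#' @param object A `thermo_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.thermo_report <- function(object, ...) {
  dat <- tidy(object)
  sub <- if (object$status == "ok") {
    sprintf(
      "F_IVYWREL = %.4f, MPT = %.2f °C",
      object$f_ivywrel, object$mpt_celsius
    )
  } else {
    object$status
  }
  ggplot2::ggplot(dat, ggplot2::aes(
    x = stats::reorder(.data$residue, -.data$frequency),
    y = .data$frequency, fill = .data$ivywrel
  )) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(
      values = c(`TRUE` = "#d1495b", `FALSE` = "grey60"),
      labels = c(`TRUE` = "IVYWREL", `FALSE` = "other"),
      name = NULL
    ) +
    ggplot2::labs(
      x = "residue", y = "pooled frequency",
      title = paste0("Amino-acid composition — ", object$sample),
      subtitle = sub
    ) +
    ggplot2::theme_minimal()
}

#' Predict optimal growth temperature from a proteome
#'
#' Pools the amino-acid composition of all coding sequences of one genome
#' and applies the linear OGT calibration (see [mpt_from_f()]).
#'
#' @param proteins Path to a protein FASTA file, a character vector of
#'   protein strings, or a protein tibble from [read_proteins()].
#' @return Predicted OGT in degrees Celsius (a single number).
#' @examples
#' predict_ogt_proteome("IVYWREL") # 602: every residue is thermal-signal
#' @export
predict_ogt_proteome <- function(proteins) {
  if (is.character(proteins) && length(proteins) == 1 && file.exists(proteins)) {
    proteins <- read_proteins(proteins)
  }
  comp <- pool_composition(proteins)
  if (comp$total == 0) {
    abort("proteome contains no countable residues")
  }
  mpt_from_f(comp$f_ivywrel)
}
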