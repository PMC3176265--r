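# End-to-end per-complex feature extraction and the command-line front end.

#' Per-residue feature table for one complex
#'
#' Runs the structural (ASA, contacts) and sequence (PSSM, entropy,
#' conservation, physicochemical) feature extractors over every residue of
#' both partners and joins them on (pdb_id, chain, resseq, icode).
#'
#' @param complex an \code{hs_structure} or PDB path.
#' @param spec a \code{\link{partner_spec}} or "A:B"-style string.
#' @param pssms optional named list (by chain id) of PSSM paths or
#'   \code{pssm_profile}s.
#' @param msas optional named list (by chain id) of FASTA MSA paths or
#'   aligned sequence vectors.
#' @param grades optional named list (by chain id) of ConSurf-style grade
#'   file paths.
#' @param n_points sphere points for the SASA quadrature.
#' @param ... contact-detection tuning parameters (see
#'   \code{\link{contact_features}}).
#' @return data.frame, one row per residue, with ASA, contact, PSSM,
#'   entropy, conservation and physicochemical columns.
#' @export
extract_features <- function(complex, spec, pssms = NULL, msas = NULL,
                             grades = NULL, n_points = 960, ...) {
  if (is.character(complex)) complex <- read_pdb(complex)
  if (is.character(spec)) spec <- parse_partner_spec(spec)
  asa <- asa_feature_table(complex, spec, n_points = n_points)
  bc <- contact_feature_table(complex, spec, ...)
  names(bc)[names(bc) == "resseq"] <- "resseq"
  out <- merge(asa, cbind(pdb_id = complex$pdb_id, bc),
               by = c("pdb_id", "chain", "resseq", "icode"), sort = FALSE)
  seqf <- do.call(rbind, lapply(unique(complex$atoms$chain), function(ch) {
    seqfeat_table(complex, ch,
                  pssm = pssms[[ch]], msa = msas[[ch]],
                  grades_file = grades[[ch]])
  }))
  out <- merge(out, seqf[, setdiff(names(seqf), "aa")],
               by = c("pdb_id", "chain", "resseq", "icode"), sort = FALSE)
  out[order(match(paste(out$chain, out$resseq, out$icode),
                  paste(complex$atoms$chain, complex$atoms$resno,
                        complex$atoms$insert)[!duplicated(
                          atom_residue_id(complex))])), , drop = FALSE]
}

#' Write a per-residue feature table as CSV
#'
#' @param tab data.frame from \code{\link{extract_features}}.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_feature_csv <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Command-line interface. Subcommands: extract, label, train, cv, predict,
## stats, baseline, ablate. Exit codes: 0 success, 1 partial failure,
## 2 invalid arguments. The installed entry script lives at
## inst/exec/hotspotr.

cli_usage <- "usage: hotspotr <command> [options]

commands:
  extract   --pdb FILE --partners A:B [--pssm CH=FILE]... [--msa CH=FILE]...
            [--n-points N] --out FILE
  label     --mutations FILE [--threshold-ddg X] --out FILE
  train     --features FILE --mutations FILE --combo G1,G2 [--threshold-ddg X]
            [--seed N] [--folds N] --out MODEL.json
  cv        --features FILE --mutations FILE --combo G1,G2 [--threshold-ddg X]
            [--seed N] [--folds N] --out REPORT.json
  predict   --model MODEL.json --features FILE --mutations FILE --combo G1,G2
            --out REPORT.json
  stats     --features FILE --mutations FILE --column NAME [--threshold-ddg X]
            --out REPORT.json
  baseline  --n N --pos N [--reps N] [--seed N] --out REPORT.json
  ablate    --features FILE --mutations FILE --combo G1,G2 [--seed N]
            [--folds N] --out REPORT.json
"

cli_parse_opts <- function(args) {
  opts <- list(); multi <- c("--pssm", "--msa")
  i <- 1
  while (i <= length(args)) {
    key <- args[i]
    if (!startsWith(key, "--"))
      stop("unexpected argument: ", key, call. = FALSE)
    if (i + 1 > length(args)) stop("missing value for ", key, call. = FALSE)
    val <- args[i + 1]
    nm <- substring(key, 3)
    if (key %in% multi) opts[[nm]] <- c(opts[[nm]], val) else opts[[nm]] <- val
    i <- i + 2
  }
  opts
}

cli_named_files <- function(entries) {
  if (is.null(entries)) return(NULL)
  out <- list()
  for (e in entries) {
    kv <- strsplit(e, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("expected CH=FILE, got ", e, call. = FALSE)
    out[[kv[1]]] <- kv[2]
  }
  out
}

cli_cfg <- function(opts) {
  svm_config(cv_folds = as.integer(opts$folds %||% 10),
             seed = as.integer(opts$seed %||% 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

cli_dataset <- function(opts) {
  feats <- utils::read.csv(opts$features, stringsAsFactors = FALSE,
                           colClasses = c(icode = "character"))
  feats$icode[is.na(feats$icode)] <- ""
  combo <- if (!is.null(opts$combo)) {
    strsplit(opts$combo, ",")[[1]]
  } else {
    ## default: every feature group fully present in the features CSV
    present <- vapply(FEATURE_GROUPS, function(cols)
      all(cols %in% names(feats)), TRUE)
    if (!any(present)) stop("no complete feature group in ", opts$features,
                            call. = FALSE)
    names(FEATURE_GROUPS)[present]
  }
  assemble_dataset(feats, opts$mutations, combo = combo,
                   threshold = as.numeric(opts[["threshold-ddg"]] %||% 1))
}

cli_write_json <- function(x, path) {
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, null = "null"), path)
}

eval_as_list <- function(rep) {
  out <- rep[c("tp", "fp", "tn", "fn", "precision", "recall", "f1")]
  if (!is.null(rep$auc)) out$auc <- rep$auc
  if (!is.null(rep$C)) { out$C <- rep$C; out$gamma <- rep$gamma }
  out
}

#' Command-line entry point
#'
#' Dispatches the subcommands wired by the installed \code{hotspotr}
#' script. Returns (rather than calls) the intended exit status so it can
#' be exercised in tests.
#'
#' @param args character vector of command-line arguments.
#' @return integer exit status: 0 success, 1 runtime failure, 2 invalid
#'   arguments.
#' @export
hotspot_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0 || args[1] %in% c("-h", "--help", "help")) {
    cat(cli_usage)
    return(if (length(args) == 0) 2L else 0L)
  }
  cmd <- args[1]
  opts <- tryCatch(cli_parse_opts(args[-1]), error = function(e) e)
  if (inherits(opts, "error")) { message(conditionMessage(opts)); return(2L) }
  need <- function(...) {
    miss <- setdiff(c(...), names(opts))
    if (length(miss) > 0)
      stop("missing required option(s): ",
           paste0("--", miss, collapse = ", "), call. = FALSE)
  }
  status <- tryCatch({
    switch(cmd,
      extract = {
        need("pdb", "partners", "out")
        tab <- extract_features(opts$pdb, opts$partners,
                                pssms = cli_named_files(opts$pssm),
                                msas = cli_named_files(opts$msa),
                                n_points = as.integer(opts[["n-points"]] %||% 960))
        write_feature_csv(tab, opts$out)
        message(sprintf("%s: %d residues, %d interface", opts$pdb,
                        nrow(tab), sum(tab$is_interface)))
        0L
      },
      label = {
        need("mutations", "out")
        m <- read_mutations(opts$mutations,
                            as.numeric(opts[["threshold-ddg"]] %||% 1))
        utils::write.csv(m, opts$out, row.names = FALSE)
        message(sprintf("%d rows: %d hot spots, %d non-hot spots",
                        nrow(m), sum(m$label), sum(!m$label)))
        0L
      },
      train = {
        need("features", "mutations", "combo", "out")
        m <- train_svm(cli_dataset(opts), cli_cfg(opts))
        save_model(m, opts$out)
        message(sprintf("model: C=%g gamma=%g", m$C, m$gamma))
        0L
      },
      cv = {
        need("features", "mutations", "combo", "out")
        rep <- cross_validate(cli_dataset(opts), cli_cfg(opts))
        cli_write_json(c(eval_as_list(rep),
                         list(seed = as.integer(opts$seed %||% 1))), opts$out)
        0L
      },
      predict = {
        need("model", "features", "mutations", "combo", "out")
        ds <- cli_dataset(opts)
        p <- predict_svm(load_model(opts$model), ds$X)
        rep <- eval_report(ds$y, p$label, p$score)
        cli_write_json(eval_as_list(rep), opts$out)
        0L
      },
      stats = {
        need("features", "mutations", "column", "out")
        ds <- cli_dataset(opts)
        v <- ds$records[[opts$column]]
        if (is.null(v)) stop("no such feature column: ", opts$column,
                             call. = FALSE)
        res <- compare_groups(v[ds$y], v[!ds$y])
        cli_write_json(res, opts$out)
        0L
      },
      baseline = {
        need("n", "pos", "out")
        res <- random_baseline(as.integer(opts$n), as.integer(opts$pos),
                               replicates = as.integer(opts$reps %||% 1000),
                               seed = as.integer(opts$seed %||% 1))
        cli_write_json(res[c("precision", "recall", "f1", "n_total",
                             "n_pos", "replicates", "seed")], opts$out)
        0L
      },
      ablate = {
        need("features", "mutations", "combo", "out")
        tab <- ablate_features(cli_dataset(opts), cli_cfg(opts))
        cli_write_json(list(f1_full = attr(tab, "f1_full"),
                            groups = tab), opts$out)
        0L
      },
      {
        message("unknown command: ", cmd); 2L
      })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    if (grepl("missing required option", conditionMessage(e))) 2L else 1L
  })
  status
}
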