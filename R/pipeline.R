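# End-to-end pipeline: batch descriptor extraction over a directory of PDB
# files, and the cross-validated classification experiment with per-fold
# fitting of every label- or population-dependent artifact (codebook,
# stepwise selection, scalers, attention weights) on training rows only.

#' Read all PDB files in a directory
#'
#' Per-file failures are logged and skipped; the batch fails only if no
#' file parses.
#'
#' @param dir directory containing `.pdb` files.
#' @return named list of `protein_structure`.
#' @export
read_pdb_dir <- function(dir) {
  files <- list.files(dir, pattern = "\\.pdb$", full.names = TRUE)
  if (!length(files)) stop("no .pdb files in ", dir)
  out <- list()
  for (f in files) {
    p <- tryCatch(suppressMessages(read_pdb_structure(f)),
                  error = function(e) {
                    message("skipping ", basename(f), ": ",
                            conditionMessage(e))
                    NULL
                  })
    if (!is.null(p)) out[[p$id]] <- p
  }
  if (!length(out)) stop("no parseable PDB files in ", dir)
  out
}

#' Extract per-protein descriptor tables
#'
#' Computes the descriptors that depend only on the individual structure
#' (contact, dihedral, chemical, gauss, ph) plus raw sub-structure sets for
#' the codebook-based descriptor. Per-protein failures yield a skipped row
#' with a message.
#'
#' @param structures named list of `protein_structure`.
#' @param descriptors subset of
#'   `c("contact", "dihedral", "chemical", "gauss", "ph")`.
#' @param ph_max_radius filtration cap for persistent homology.
#' @param properties chemical property table.
#' @return named list of feature data.frames (id + named columns).
#' @export
extract_descriptors <- function(structures,
                                descriptors = c("contact", "dihedral",
                                                "chemical", "gauss", "ph"),
                                ph_max_radius = 16,
                                properties = default_property_table()) {
  descriptors <- match.arg(descriptors, several.ok = TRUE)
  fns <- list(
    contact = function(p) contact_descriptor(p),
    dihedral = function(p) dihedral_features(dihedral_series(p)),
    chemical = function(p) chemical_features(p, properties),
    gauss = function(p) gauss_integrals(p),
    ph = function(p) ph_features(persistent_homology(p, ph_max_radius))
  )
  out <- list()
  for (d in descriptors) {
    rows <- list()
    for (id in names(structures)) {
      v <- tryCatch(suppressWarnings(fns[[d]](structures[[id]])),
                    error = function(e) {
                      message("descriptor ", d, " failed for ", id, ": ",
                              conditionMessage(e))
                      NULL
                    })
      if (!is.null(v)) rows[[id]] <- v
    }
    if (!length(rows)) stop("descriptor ", d, " failed for every protein")
    out[[d]] <- data.frame(id = names(rows), do.call(rbind, rows),
                           check.names = FALSE, row.names = NULL,
                           stringsAsFactors = FALSE)
  }
  out
}

# fold-wise feature construction for the codebook descriptor
fold_substructure_features <- function(sub_sets, train_ids, local_t,
                                       global_t) {
  cb <- build_codebook(sub_sets[train_ids], local_t, global_t)
  feats <- t(vapply(sub_sets, substructure_frequency, codebook = cb,
                    numeric(nrow(cb$centroids))))
  list(codebook = cb,
       table = data.frame(id = names(sub_sets), feats,
                          check.names = FALSE, row.names = NULL,
                          stringsAsFactors = FALSE))
}

#' Run the cross-validated classification experiment
#'
#' 10-fold stratified cross-validation over a set of structures. Every
#' artifact that depends on more than one protein or on the labels --
#' sub-structure codebooks, stepwise selection of the contact descriptor,
#' block scalers, attention-network weights -- is fitted on the training
#' rows of each fold only. Reports per-descriptor and fused results.
#'
#' @param structures named list of `protein_structure`.
#' @param labels data.frame with columns `id`, `class` covering the
#'   structures.
#' @param descriptors descriptor names among `c("contact", "dihedral",
#'   "chemical", "gauss", "ph", "substructure", "gat")`.
#' @param model `"rf"` or `"svm"`.
#' @param fuse fusion methods among
#'   `c("vote", "weighted", "concat", "mkl")` (default vote + concat).
#' @param n_folds folds (default 10).
#' @param seed seed controlling the fold plan and all model fits.
#' @param rf_grid,svm_grid hyperparameter grids.
#' @param select_contact apply stepwise discriminant selection to the
#'   contact descriptor per fold (default TRUE).
#' @param codebook_grid list of `local_t` / `global_t` values searched per
#'   fold for the sub-structure codebook (first values used directly when
#'   lengths are 1).
#' @param gat_epochs training epochs for the attention encoder.
#' @return object of class `slc_experiment`.
#' @export
run_experiment <- function(structures, labels,
                           descriptors = c("dihedral", "gauss"),
                           model = c("rf", "svm"),
                           fuse = c("vote", "concat"),
                           n_folds = 10L, seed = 1L,
                           rf_grid = c(100, 300, 500, 1000),
                           svm_grid = default_svm_grid(),
                           select_contact = TRUE,
                           codebook_grid = list(local_t = 10, global_t = 20),
                           gat_epochs = 150L) {
  model <- match.arg(model)
  fuse <- if (is.null(fuse)) character(0) else
    match.arg(fuse, c("vote", "weighted", "concat", "mkl"),
              several.ok = TRUE)
  ids <- names(structures)
  labels <- labels[match(ids, labels$id), , drop = FALSE]
  if (anyNA(labels$class)) stop("labels missing for some structures")
  y <- labels$class
  lv <- canonical_levels(y)

  simple <- intersect(descriptors,
                      c("contact", "dihedral", "chemical", "gauss", "ph"))
  tables <- if (length(simple)) {
    extract_descriptors(structures, simple)
  } else list()
  need_subs <- any(c("substructure") %in% descriptors)
  sub_sets <- if (need_subs) {
    lapply(structures, extract_substructures)
  } else NULL
  graphs <- if ("gat" %in% descriptors) lapply(structures, build_graph)
  else NULL

  plan <- make_cv_plan(y, n_folds = n_folds, seed = seed)
  fit_fun <- if (model == "rf") {
    function(Xt, yt, Xv) fit_predict_rf(Xt, yt, Xv, grid = rf_grid,
                                        seed = seed)
  } else {
    function(Xt, yt, Xv) fit_predict_svm(Xt, yt, Xv, grid = svm_grid,
                                         seed = seed)
  }

  n <- length(ids)
  desc_scores <- lapply(descriptors, function(d) {
    matrix(NA_real_, n, length(lv), dimnames = list(ids, lv))
  })
  names(desc_scores) <- descriptors
  fuse_scores <- lapply(fuse, function(f) {
    matrix(NA_real_, n, length(lv), dimnames = list(ids, lv))
  })
  names(fuse_scores) <- fuse
  hyper <- list()
  mkl_weights <- list()

  for (fold in seq_along(plan)) {
    val <- plan[[fold]]
    train <- setdiff(seq_len(n), val)
    fold_mats <- list()
    for (d in descriptors) {
      if (d %in% names(tables)) {
        m <- feature_matrix(tables[[d]])
        m <- m[match(ids, rownames(m)), , drop = FALSE]
      } else if (d == "substructure") {
        fs <- fold_substructure_features(sub_sets, ids[train],
                                         codebook_grid$local_t[1],
                                         codebook_grid$global_t[1])
        m <- feature_matrix(fs$table)[ids, , drop = FALSE]
      } else if (d == "gat") {
        tg <- train_gat(graphs[train], y[train], epochs = gat_epochs,
                        seed = seed)
        m <- t(vapply(graphs, function(g) {
          suppressWarnings(gat_forward(g, tg$params))
        }, numeric(84)))
      } else {
        stop("unknown descriptor ", d)
      }
      if (d == "contact" && select_contact) {
        sel <- stepwise_discriminant(m[train, , drop = FALSE], y[train])
        if (length(sel$kept)) m <- m[, sel$kept, drop = FALSE]
        hyper[[paste0("fold", fold, "_contact_kept")]] <- ncol(m)
      }
      fold_mats[[d]] <- m
      sc <- fit_fun(m[train, , drop = FALSE], y[train],
                    m[val, , drop = FALSE])
      desc_scores[[d]][val, ] <- sc
      hyper[[paste0("fold", fold, "_", d)]] <- attr(sc, "best")
      attr(desc_scores[[d]], paste0("acc_fold", fold)) <-
        attr(sc, "inner_accuracy")
    }
    # fusion
    if ("vote" %in% fuse && length(descriptors) >= 2L) {
      fuse_scores[["vote"]][val, ] <- vote_scores(
        lapply(desc_scores, function(s) s[val, , drop = FALSE]))
    }
    if ("weighted" %in% fuse && length(descriptors) >= 2L) {
      accs <- vapply(descriptors, function(d) {
        attr(desc_scores[[d]], paste0("acc_fold", fold))
      }, numeric(1))
      fuse_scores[["weighted"]][val, ] <- weighted_vote(
        lapply(desc_scores, function(s) s[val, , drop = FALSE]), accs)
    }
    if ("concat" %in% fuse && length(descriptors) >= 2L) {
      scalers <- lapply(fold_mats, function(m) {
        fit_scaler(m[train, , drop = FALSE])
      })
      Xt <- do.call(cbind, Map(function(m, sc) apply_scaler(
        m[train, , drop = FALSE], sc), fold_mats, scalers))
      Xv <- do.call(cbind, Map(function(m, sc) apply_scaler(
        m[val, , drop = FALSE], sc), fold_mats, scalers))
      fuse_scores[["concat"]][val, ] <- fit_fun(Xt, y[train], Xv)
    }
    if ("mkl" %in% fuse && length(descriptors) >= 2L) {
      mk <- multikernel_svm(
        lapply(fold_mats, function(m) m[train, , drop = FALSE]),
        lapply(fold_mats, function(m) m[val, , drop = FALSE]),
        y[train], seed = seed)
      fuse_scores[["mkl"]][val, ] <- mk$scores
      mkl_weights[[paste0("fold", fold)]] <- mk$weights
    }
  }

  desc_eval <- lapply(desc_scores, evaluate, y_true = y)
  fuse_eval <- lapply(fuse_scores, function(s) {
    if (anyNA(s)) NULL else evaluate(s, y)
  })
  fuse_eval <- Filter(Negate(is.null), fuse_eval)
  structure(list(descriptor_scores = desc_scores,
                 fusion_scores = fuse_scores,
                 descriptor_eval = desc_eval,
                 fusion_eval = fuse_eval,
                 labels = labels, classes = lv, plan = plan,
                 model = model, seed = seed, hyper = hyper,
                 mkl_weights = mkl_weights),
            class = "slc_experiment")
}

#' @export
print.slc_experiment <- function(x, ...) {
  cat("subcellular-location experiment (", x$model, ", ",
      length(x$plan), "-fold CV, n = ", nrow(x$labels), ")\n", sep = "")
  for (d in names(x$descriptor_eval)) {
    e <- x$descriptor_eval[[d]]
    cat(sprintf("  %-14s accuracy %.4f  macro-F1 %.4f\n", d,
                e$accuracy, e$f1_macro))
  }
  for (f in names(x$fusion_eval)) {
    e <- x$fusion_eval[[f]]
    cat(sprintf("  fused(%-7s) accuracy %.4f  macro-F1 %.4f\n", f,
                e$accuracy, e$f1_macro))
  }
  invisible(x)
}

#' @export
summary.slc_experiment <- function(object, ...) {
  print(object)
  cat("\nconfusion matrices:\n")
  for (d in names(object$descriptor_eval)) {
    cat("\n", d, ":\n", sep = "")
    print(object$descriptor_eval[[d]]$confusion)
  }
  invisible(object)
}
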