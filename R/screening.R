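#' Physicochemical library filters
#'
#' Applies the screening filters used to restrict a purchasable-compound
#' library before prediction: molecular weight strictly below `mw_max`
#' (average atomic masses, implicit hydrogens included) and an exclusive
#' element whitelist -- every atom must be one of `allowed_elements`.
#' Defaults: MW < 325 and atoms C, O, N, H, S.
#'
#' Decisions are per molecule and order-invariant. Multi-fragment SMILES
#' (containing `.`) fail with reason `"multifragment"`; unparseable SMILES
#' fail with reason `"parse"` rather than raising an error.
#'
#' @param mols Compound table (columns `id`, `smiles`).
#' @param mw_max Upper molecular-weight bound, exclusive (default 325).
#' @param allowed_elements Character vector of allowed element symbols
#'   (default `c("C", "O", "N", "H", "S")`).
#' @return A data.frame (`id`, `smiles`, `pass`, `reason`, `mw`), one row
#'   per molecule in input order; `reason` is `""` for passing molecules,
#'   else one of `"multifragment"`, `"parse"`, `"element:<X>"`,
#'   `"mw:<value>"`. `mw` is `NA` for unparseable molecules.
#' @examples
#' \donttest{
#' filter_library(data.frame(id = c("ea", "clb"),
#'                           smiles = c("CCOC(C)=O", "Clc1ccccc1")))
#' }
#' @export
filter_library <- function(mols, mw_max = 325,
                           allowed_elements = c("C", "O", "N", "H", "S")) {
  smi <- as.character(mols$smiles)
  uniq <- unique(smi)
  verdict <- lapply(uniq, filter_one_smiles, mw_max = mw_max,
                    allowed = allowed_elements)
  names(verdict) <- uniq
  res <- verdict[smi]
  data.frame(id = as.character(mols$id), smiles = smi,
             pass = vapply(res, `[[`, logical(1), "pass"),
             reason = vapply(res, `[[`, character(1), "reason"),
             mw = vapply(res, `[[`, numeric(1), "mw"),
             stringsAsFactors = FALSE, row.names = NULL)
}

filter_one_smiles <- function(s, mw_max, allowed) {
  if (grepl(".", s, fixed = TRUE))
    return(list(pass = FALSE, reason = "multifragment", mw = NA_real_))
  sdf <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(c(mol = s))),
                  error = function(e) NULL)
  if (is.null(sdf) || !all(ChemmineR::validSDF(sdf)))
    return(list(pass = FALSE, reason = "parse", mw = NA_real_))
  mw <- ChemmineR::propOB(sdf)$MW[1]
  elements <- sdf_elements(sdf[[1]])
  bad <- setdiff(elements, allowed)
  if (length(bad))
    return(list(pass = FALSE, reason = paste0("element:", bad[1]), mw = mw))
  if (!(mw < mw_max))
    return(list(pass = FALSE, reason = sprintf("mw:%.2f", mw), mw = mw))
  list(pass = TRUE, reason = "", mw = mw)
}

#' Screen a compound library with a trained model
#'
#' Runs the virtual screen: filter the library ([filter_library()]),
#' compute (or look up) descriptors for the passing molecules, apply the
#' model's training scaling, predict activity scores, and rank the passing
#' molecules by descending score (ties broken by id). The library is
#' processed in chunks of `chunk_size` molecules, so memory per chunk is
#' constant and chunk size never changes the result.
#'
#' @param model An `orn_svm` model.
#' @param library Compound table of the library to screen.
#' @param descriptors Optional raw `descriptor_matrix` covering the library
#'   molecules (by id); when supplied (e.g. simulated or pre-computed
#'   tables), descriptor computation from SMILES is skipped.
#' @param mw_max,allowed_elements Filter settings (see [filter_library()]).
#' @param chunk_size Molecules per processing chunk (default 10000).
#' @return An object of class `screen_result`: `table` (rank, id, smiles,
#'   score, mw, pass, reason; passing molecules first, ranked 1..n_passed),
#'   `n_library`, `n_passed`, `attrition` (named count per fail reason).
#' @examples
#' sim <- gen_training_set(chem_sim_config(n_descriptors = 40, seed = 1))
#' m <- scale_matrix(clean_matrix(sim$matrix))
#' fit <- train_svm(m, sim$truth$informative, sim$compounds$activity)
#' lib <- gen_library(chem_sim_config(n_descriptors = 40, seed = 1),
#'                    n_library = 100, n_planted_active = 10, seed = 6)
#' res <- screen_library(fit, lib$compounds, descriptors = lib$matrix)
#' head(res$table)
#' @export
screen_library <- function(model, library, descriptors = NULL, mw_max = 325,
                           allowed_elements = c("C", "O", "N", "H", "S"),
                           chunk_size = 10000) {
  stopifnot(inherits(model, "orn_svm"))
  n <- nrow(library)
  if (n == 0L)
    return(structure(list(table = data.frame(rank = integer(0),
                                             id = character(0),
                                             smiles = character(0),
                                             score = numeric(0),
                                             mw = numeric(0),
                                             pass = logical(0),
                                             reason = character(0)),
                          n_library = 0L, n_passed = 0L,
                          attrition = integer(0)),
                     class = "screen_result"))
  if (chunk_size < 1L) stopf("chunk_size must be >= 1")
  chunks <- split(seq_len(n), ceiling(seq_len(n) / chunk_size))
  parts <- lapply(chunks, function(idx) {
    chunk <- library[idx, , drop = FALSE]
    flt <- filter_library(chunk, mw_max = mw_max,
                          allowed_elements = allowed_elements)
    flt$score <- NA_real_
    if (any(flt$pass)) {
      passing <- chunk[flt$pass, , drop = FALSE]
      dm <- if (is.null(descriptors)) {
        compute_descriptors(passing)
      } else {
        missing_ids <- setdiff(passing$id, rownames(descriptors$values))
        if (length(missing_ids))
          stopf("descriptor matrix lacks library molecule(s): %s",
                paste(utils::head(missing_ids, 5), collapse = ", "))
        descriptor_matrix(descriptors$values[passing$id, , drop = FALSE],
                          scaling = descriptors$scaling,
                          provenance = descriptors$provenance)
      }
      flt$score[flt$pass] <- unname(predict(model, dm))
    }
    flt
  })
  all <- do.call(rbind, parts)
  rownames(all) <- NULL
  passed <- all[all$pass, , drop = FALSE]
  failed <- all[!all$pass, , drop = FALSE]
  ord <- order(-passed$score, passed$id)
  passed <- passed[ord, , drop = FALSE]
  out <- rbind(
    data.frame(rank = seq_len(nrow(passed)), passed,
               stringsAsFactors = FALSE),
    if (nrow(failed)) data.frame(rank = NA_integer_, failed,
                                 stringsAsFactors = FALSE))
  rownames(out) <- NULL
  structure(list(table = out[, c("rank", "id", "smiles", "score", "mw",
                                 "pass", "reason")],
                 n_library = n, n_passed = nrow(passed),
                 attrition = table(failed$reason)),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("screen_result: %d / %d molecules passed filters\n",
              x$n_passed, x$n_library))
  if (length(x$attrition)) {
    cat("  attrition:\n")
    for (r in names(x$attrition))
      cat(sprintf("    %-14s %d\n", r, x$attrition[[r]]))
  }
  invisible(x)
}

#' Write screening results
#'
#' Writes the ranked passing molecules as tab-delimited text and the
#' rejected molecules (with fail reasons) to a companion
#' `<path>.rejected` file.
#'
#' @param x A `screen_result`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_screen_result <- function(x, path) {
  tab <- x$table
  write.table(tab[tab$pass, c("rank", "id", "smiles", "score", "mw")],
              path, sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(tab[!tab$pass, c("id", "smiles", "mw", "reason")],
              paste0(path, ".rejected"), sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}
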