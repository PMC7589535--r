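#' Read a structural ensemble from PDB files
#'
#' Reads one or more PDB files (single- or multi-MODEL) into an [ensemble()].
#' One conformer is created per MODEL per file, in input order.  Alternate
#' locations are resolved by keeping the highest-occupancy variant (ties go to
#' altloc 'A'); insertion codes are preserved in the topology key; HETATM
#' records are retained but excluded from the C-alpha selection.  All
#' conformers must expose an identical C-alpha topology; mismatches raise an
#' error naming the offending conformer.
#'
#' @param paths Character vector of PDB file paths.
#' @param chain_filter Optional chain identifier; only matching chains are
#'   kept.
#' @return An [ensemble()].
#' @export
read_ensemble <- function(paths, chain_filter = NULL) {
  confs <- list()
  for (path in paths) {
    pdb <- tryCatch(
      bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE),
      error = function(e) {
        abort(paste0("cannot parse PDB file '", path, "': ",
                     conditionMessage(e)))
      }
    )
    at <- pdb$atom
    if (is.null(at) || nrow(at) == 0) {
      abort(paste0("cannot parse PDB file '", path,
                   "': no atom records found"))
    }
    at$insert[is.na(at$insert)] <- ""
    at$alt[is.na(at$alt)] <- ""
    at$o[is.na(at$o)] <- 1
    if (!is.null(chain_filter)) {
      keep_chain <- at$chain %in% chain_filter
      if (!any(keep_chain)) {
        abort(paste0("no atoms on chain '", chain_filter, "' in '", path, "'"))
      }
    } else {
      keep_chain <- rep(TRUE, nrow(at))
    }

    # Altloc resolution: per (chain, resno, insert, elety) keep the highest
    # occupancy, ties resolved toward 'A' then alphabetically.
    key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
    ord <- order(-at$o, at$alt != "A", at$alt, seq_len(nrow(at)))
    first_of_key <- !duplicated(key[ord])
    keep_alt <- logical(nrow(at))
    keep_alt[ord[first_of_key]] <- TRUE

    keep <- keep_chain & keep_alt
    rows <- which(keep)

    n_models <- nrow(pdb$xyz)
    for (m in seq_len(n_models)) {
      xyz <- matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)
      atoms <- tibble::tibble(
        chain = at$chain[rows],
        resid = as.integer(at$resno[rows]),
        insert = at$insert[rows],
        resname = at$resid[rows],
        elety = at$elety[rows],
        x = xyz[rows, 1],
        y = xyz[rows, 2],
        z = xyz[rows, 3],
        het = at$type[rows] == "HETATM"
      )
      label <- if (n_models > 1) {
        paste0(basename(path), "#", m)
      } else {
        basename(path)
      }
      confs[[length(confs) + 1]] <- conformer(atoms, label = label)
    }
  }
  ensemble(confs)
}

#' Write an ensemble as a multi-model PDB file
#'
#' @param ens An [ensemble()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_ensemble <- function(ens, path) {
  blocks <- character(0)
  for (m in seq_along(ens)) {
    a <- ens[[m]]$atoms
    tmp <- tempfile(fileext = ".pdb")
    on.exit(unlink(tmp), add = TRUE)
    bio3d::write.pdb(
      file = tmp,
      xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
      type = ifelse(a$het, "HETATM", "ATOM"),
      resno = a$resid,
      resid = a$resname,
      eleno = seq_len(nrow(a)),
      elety = a$elety,
      chain = a$chain,
      insert = ifelse(a$insert == "", NA, a$insert)
    )
    lines <- readLines(tmp)
    lines <- lines[grepl("^(ATOM|HETATM|TER)", lines)]
    blocks <- c(blocks, sprintf("MODEL     %4d", m), lines, "ENDMDL")
  }
  writeLines(c(blocks, "END"), path)
  invisible(path)
}

#' Write a labelled square matrix (RMSD, lDDT) as CSV
#'
#' @param mat Square numeric matrix with conformer labels as dimnames.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_matrix_csv <- function(mat, path) {
  df <- as.data.frame(mat)
  df <- cbind(conformer = rownames(mat), df)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
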