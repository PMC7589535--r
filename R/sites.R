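#' Dye labeling-site definition
#'
#' Describes where and how a fluorophore is attached: the attachment residue
#' and atom, the flexible-linker geometry and the dye radius (one value, or
#' three for the three-radius dye model).  The defaults describe a typical
#' single-molecule FRET dye (Alexa-class) on a long maleimide linker.
#'
#' @param chain Chain identifier.
#' @param resid Attachment residue number.
#' @param atom Attachment atom name (default `"CB"`).
#' @param linker_length Linker length in Angstrom (> 0). Default 20.
#' @param linker_width Linker width in Angstrom (> 0). Default 4.5.
#' @param dye_radii One or three dye radii in Angstrom (> 0).
#'   Default `c(3.5, 4.5, 1.5)`.
#' @param role `"donor"` or `"acceptor"`.
#' @return A `labeling_site` object.
#' @export
labeling_site <- function(chain, resid, atom = "CB",
                          linker_length = 20, linker_width = 4.5,
                          dye_radii = c(3.5, 4.5, 1.5),
                          role = c("donor", "acceptor")) {
  role <- match.arg(role)
  if (linker_length <= 0 || linker_width <= 0 || any(dye_radii <= 0)) {
    abort("linker length, linker width and dye radii must be positive")
  }
  if (!length(dye_radii) %in% c(1, 3)) {
    abort("dye_radii must have one or three values")
  }
  x <- list(chain = as.character(chain), resid = as.integer(resid),
            atom = atom, linker_length = linker_length,
            linker_width = linker_width, dye_radii = dye_radii, role = role)
  class(x) <- "labeling_site"
  x
}

#' @export
print.labeling_site <- function(x, ...) {
  cat("<labeling_site> ", site_id(x), " (", x$role, "), linker ",
      x$linker_length, "/", x$linker_width, " A, radii ",
      paste(x$dye_radii, collapse = "/"), " A\n", sep = "")
  invisible(x)
}

site_id <- function(site) {
  paste(site$chain, site$resid, site$atom, sep = ":")
}

parse_site_id <- function(id, role = "donor", ...) {
  parts <- strsplit(id, ":", fixed = TRUE)[[1]]
  if (length(parts) != 3) abort(paste0("malformed site id '", id, "'"))
  labeling_site(chain = parts[1], resid = as.integer(parts[2]),
                atom = parts[3], role = role, ...)
}

#' FRET pair definition
#'
#' A donor and an acceptor labeling site together with the Foerster radius
#' of the dye pair.
#'
#' @param pair_id Unique identifier.
#' @param donor,acceptor [labeling_site()] objects (must differ).
#' @param r0 Foerster radius in Angstrom (> 0). Default 52.
#' @return A `fret_pair` object.
#' @export
fret_pair <- function(pair_id, donor, acceptor, r0 = 52) {
  if (r0 <= 0) abort("Foerster radius must be positive")
  if (identical(site_id(donor), site_id(acceptor))) {
    abort("donor and acceptor sites must differ")
  }
  x <- list(pair_id = as.character(pair_id), donor = donor,
            acceptor = acceptor, r0 = r0)
  class(x) <- "fret_pair"
  x
}

#' @export
print.fret_pair <- function(x, ...) {
  cat("<fret_pair> ", x$pair_id, ": ", site_id(x$donor), " -> ",
      site_id(x$acceptor), ", R0 = ", x$r0, " A\n", sep = "")
  invisible(x)
}

pair_ids <- function(pairs) {
  vapply(pairs, function(p) p$pair_id, character(1))
}

unique_sites <- function(pairs) {
  sites <- list()
  for (p in pairs) {
    for (s in list(p$donor, p$acceptor)) {
      sites[[site_id(s)]] <- s
    }
  }
  sites
}

#' Read and write candidate-pair pool CSV files
#'
#' The pool file has columns `pair_id`, `donor`, `acceptor` (sites as
#' `chain:resid:atom`) and `r0`.  Site exclusion files have columns `site`
#' and `reason`; excluded sites remove every pair touching them.
#'
#' @param path CSV file path.
#' @param exclusions Optional exclusion data frame (`site`, `reason`) or path
#'   to such a CSV.
#' @param ... Dye parameters passed to [labeling_site()] for every site.
#' @return A list of [fret_pair()] objects.
#' @export
read_pair_pool <- function(path, exclusions = NULL, ...) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("pair_id", "donor", "acceptor", "r0")
  if (!all(needed %in% names(df))) {
    abort(paste0("pool file must have columns: ",
                 paste(needed, collapse = ", ")))
  }
  if (is.character(exclusions)) {
    exclusions <- read.csv(exclusions, stringsAsFactors = FALSE)
  }
  excluded <- character(0)
  if (!is.null(exclusions)) {
    excluded <- as.character(exclusions$site)
  }
  pairs <- list()
  for (i in seq_len(nrow(df))) {
    d_id <- df$donor[i]
    a_id <- df$acceptor[i]
    if (d_id %in% excluded || a_id %in% excluded) {
      inform(paste0("pair ", df$pair_id[i],
                    " dropped: site excluded by prior knowledge"))
      next
    }
    pairs[[length(pairs) + 1]] <- fret_pair(
      df$pair_id[i],
      donor = parse_site_id(d_id, role = "donor", ...),
      acceptor = parse_site_id(a_id, role = "acceptor", ...),
      r0 = df$r0[i]
    )
  }
  pairs
}

#' @rdname read_pair_pool
#' @param pairs List of [fret_pair()] objects.
#' @export
write_pair_pool <- function(pairs, path) {
  df <- data.frame(
    pair_id = pair_ids(pairs),
    donor = vapply(pairs, function(p) site_id(p$donor), character(1)),
    acceptor = vapply(pairs, function(p) site_id(p$acceptor), character(1)),
    r0 = vapply(pairs, function(p) p$r0, numeric(1))
  )
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
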