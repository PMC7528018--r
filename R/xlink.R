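# Crosslinking-MS restraint tables: ingestion, score filtering, mapping onto
# assemblies, violation counting and per-fit satisfaction.

#' Crosslink mapping configuration
#'
#' @param ld_min minimum linear-discriminant (ld) confidence score; links
#'   with \code{ld_score >= ld_min} are kept (inclusive threshold; the
#'   conventional cutoff for xQuest-style exports is 40).
#' @param max_distance maximum compatible C-alpha--C-alpha distance in
#'   angstrom (35 for a DSS crosslinker); links longer than this are flagged
#'   violated. Violations are reported, never used to hard-reject fits.
#' @param chain_map named character vector (or list) mapping protein names in
#'   the table to chain ids in the structure; a protein may map to several
#'   chain copies, in which case the minimum distance over copies is used.
#' @return An object of class \code{xlink_config}.
#' @export
xlink_config <- function(ld_min = 40, max_distance = 35, chain_map = c()) {
  stopifnot(is.finite(ld_min), max_distance > 0)
  structure(list(ld_min = ld_min, max_distance = max_distance,
                 chain_map = chain_map),
            class = "xlink_config")
}

# normalize a header name: lowercase, drop non-alphanumerics
norm_name <- function(x) gsub("[^a-z0-9]", "", tolower(x))

#' Read an xQuest-style crosslink table
#'
#' Tab- or comma-separated with named columns \code{protein1},
#' \code{residue1}, \code{protein2}, \code{residue2}, \code{ld score} (or
#' \code{ld-Score}; header matching ignores case and punctuation) and
#' optionally \code{link type} (inter / intra / monolink). Rows with
#' unparseable residue numbers are rejected with row-level diagnostics
#' (attribute \code{"rejected"}); monolinks carry one residue only.
#'
#' @param path path to the table.
#' @return Data frame of class \code{xlink_table} with columns
#'   \code{protein1}, \code{residue1}, \code{protein2}, \code{residue2},
#'   \code{ld_score}, \code{link_type}.
#' @export
read_xlink_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "\"", comment.char = "")
  nm <- norm_name(names(df))
  pick <- function(key) {
    i <- which(nm == key)
    if (length(i) == 0) stop("missing mandatory column: ", key)
    df[[i[1]]]
  }
  p1 <- as.character(pick("protein1"))
  r1 <- pick("residue1")
  p2 <- as.character(pick("protein2"))
  r2 <- pick("residue2")
  ld <- suppressWarnings(as.numeric(pick("ldscore")))
  lt <- if (any(nm == "linktype")) as.character(df[[which(nm == "linktype")[1]]])
        else rep(NA_character_, nrow(df))
  to_res <- function(x) suppressWarnings(as.integer(as.character(x)))
  r1i <- to_res(r1)
  r2i <- to_res(r2)
  mono <- (!is.na(lt) & lt == "monolink") |
    (is.na(lt) & (is.na(r2i) | !nzchar(trimws(as.character(p2)))))
  lt[is.na(lt)] <- ifelse(mono[is.na(lt)], "monolink",
                          ifelse(p1[is.na(lt)] == p2[is.na(lt)], "intra",
                                 "inter"))
  bad <- is.na(r1i) | (!mono & is.na(r2i)) |
    (!is.na(r1i) & r1i < 1) | (!mono & !is.na(r2i) & r2i < 1) | is.na(ld)
  out <- data.frame(protein1 = p1, residue1 = r1i, protein2 = p2,
                    residue2 = r2i, ld_score = ld, link_type = lt,
                    stringsAsFactors = FALSE)[!bad, , drop = FALSE]
  rownames(out) <- NULL
  if (any(bad)) {
    attr(out, "rejected") <- data.frame(row = which(bad),
                                        reason = "unparseable residue or score")
    warning(sum(bad), " row(s) rejected (unparseable residue or score)")
  }
  class(out) <- c("xlink_table", "data.frame")
  out
}

#' Write a crosslink table (tab-separated)
#' @param links an \code{xlink_table} data frame.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
write_xlink_table <- function(links, path) {
  df <- as.data.frame(links)
  names(df) <- c("protein1", "residue1", "protein2", "residue2", "ld score",
                 "link type")[seq_along(names(df))]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter crosslinks by ld score
#'
#' Keeps links with \code{ld_score >= ld_min} (inclusive). Monolinks pass the
#' filter like any other row but are excluded from distance analysis
#' downstream.
#' @param links an \code{xlink_table}.
#' @param ld_min inclusive threshold.
#' @return The filtered \code{xlink_table}.
#' @export
filter_crosslinks <- function(links, ld_min) {
  out <- links[links$ld_score >= ld_min, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("xlink_table", "data.frame")
  out
}

# C-alpha position(s) of (protein, residue) under a chain map; NULL if the
# residue has no C-alpha in any mapped chain
calpha_lookup <- function(atoms, chain_map, protein, residue) {
  chains <- if (is.list(chain_map)) {
    if (protein %in% names(chain_map)) unlist(chain_map[[protein]]) else NULL
  } else {
    unname(chain_map[names(chain_map) == protein])
  }
  if (is.null(chains) || length(chains) == 0) return(NULL)
  hit <- atoms$chain %in% chains & atoms$resno == residue &
    trimws(atoms$elety) == "CA" & atoms$insert == ""
  if (!any(hit)) return(NULL)
  as.matrix(atoms[hit, c("x", "y", "z"), drop = FALSE])
}

#' Map crosslinks onto an assembly
#'
#' Applies the ld-score filter, then maps every distance link (monolinks are
#' excluded from distance analysis) onto the assembly: a link is mappable iff
#' both residues exist with C-alpha atoms in chains covered by the chain map;
#' the distance is the Euclidean C-alpha--C-alpha distance (minimum over
#' chain copies when a protein maps to several); a link is violated iff its
#' distance exceeds \code{config$max_distance}. Links whose protein has no
#' chain-map entry are reported unmappable, never silently dropped.
#'
#' @param assembly an \code{atomic_model} of the assembled pose.
#' @param links an \code{xlink_table}.
#' @param config an \code{xlink_config}.
#' @return List of class \code{xlink_mapping} with \code{per_link} (data
#'   frame: mappable, distance, violated per filtered link) and
#'   \code{totals} (\code{n_input}, \code{n_pass_filter}, \code{n_mapped},
#'   \code{n_violated}).
#' @export
map_crosslinks <- function(assembly, links, config) {
  if (nrow(assembly$atoms) == 0) stop("empty assembly")
  n_input <- nrow(links)
  kept <- filter_crosslinks(links, config$ld_min)
  n_pass <- nrow(kept)
  per <- kept
  per$mappable <- FALSE
  per$distance <- NA_real_
  per$violated <- FALSE
  for (i in seq_len(nrow(kept))) {
    if (kept$link_type[i] == "monolink") next
    ca1 <- calpha_lookup(assembly$atoms, config$chain_map,
                         kept$protein1[i], kept$residue1[i])
    ca2 <- calpha_lookup(assembly$atoms, config$chain_map,
                         kept$protein2[i], kept$residue2[i])
    if (is.null(ca1) || is.null(ca2)) next
    d2 <- outer(rowSums(ca1^2), rowSums(ca2^2), "+") - 2 * ca1 %*% t(ca2)
    d <- sqrt(max(0, min(d2)))
    per$mappable[i] <- TRUE
    per$distance[i] <- d
    per$violated[i] <- d > config$max_distance
  }
  totals <- list(n_input = n_input, n_pass_filter = n_pass,
                 n_mapped = sum(per$mappable),
                 n_violated = sum(per$violated))
  structure(list(per_link = per, totals = totals, config = config),
            class = "xlink_mapping")
}

#' @export
print.xlink_mapping <- function(x, ...) {
  t <- x$totals
  cat(sprintf("xlink_mapping: %d input, %d pass ld >= %g, %d mapped, %d violated (> %g A)\n",
              t$n_input, t$n_pass_filter, x$config$ld_min, t$n_mapped,
              t$n_violated, x$config$max_distance))
  invisible(x)
}

#' Crosslink satisfaction fraction
#'
#' \code{(n_mapped - n_violated) / n_mapped} over the mappable distance
#' links.
#' @param assembly an \code{atomic_model}, or a precomputed
#'   \code{xlink_mapping} (in which case \code{links}/\code{config} are not
#'   needed).
#' @param links an \code{xlink_table}.
#' @param config an \code{xlink_config}.
#' @return Fraction in \[0, 1\].
#' @export
satisfaction_fraction <- function(assembly, links = NULL, config = NULL) {
  res <- if (inherits(assembly, "xlink_mapping")) assembly
         else map_crosslinks(assembly, links, config)
  if (res$totals$n_mapped == 0) stop("no mappable crosslinks")
  (res$totals$n_mapped - res$totals$n_violated) / res$totals$n_mapped
}
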