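#' DSSAT *.SOL soil file reader and writer
#'
#' The *.SOL dialect is a fixed-width text format: per profile, a `*`
#' header line (ID, source, texture label, profile depth, description), a
#' `@SITE` line, a surface-parameter record and one record per soil
#' horizon. `-99` marks a value the crop model should replace with its
#' default. The exact column widths and printed precisions are frozen in
#' the two descriptor tables below; "bit-exact" output is defined by these
#' descriptors. Files are written as ASCII with LF line endings and no
#' trailing whitespace so reruns are byte-identical.
#'
#' @name sol_io
NULL

# Field descriptors: one row per column, fixed width, printed precision
# (digits = NA means a character or integer field).
SOL_SURFACE_FORMAT <- data.frame(
  name = c("SCOM", "SALB", "SLU1", "SLDR", "SLRO", "SLNF", "SLPF",
    "SMHB", "SMPX", "SMKE"),
  width = 6L,
  digits = c(NA, 2L, 1L, 2L, 1L, 2L, 2L, NA, NA, NA),
  numeric = c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
  stringsAsFactors = FALSE
)

SOL_LAYER_FORMAT <- data.frame(
  name = c("SLB", "SLMH", "SLLL", "SDUL", "SSAT", "SRGF", "SSKS", "SBDM",
    "SLOC", "SLCL", "SLSI", "SLCF", "SLNI", "SLHW", "SLHB", "SCEC"),
  width = 6L,
  digits = c(0L, NA, 3L, 3L, 3L, 3L, 2L, 2L, 2L, 1L, 1L, 1L, 3L, 1L, 1L, 1L),
  numeric = c(TRUE, FALSE, rep(TRUE, 14)),
  stringsAsFactors = FALSE
)

#' Construct a soil profile object
#'
#' @param profile_id 10-character (or shorter) profile identifier.
#' @param source Data-source tag written in the header.
#' @param texture_label Short texture code for the header (e.g. "C", "L").
#' @param depth_cm Profile depth, cm (bottom of the last layer).
#' @param description Free-text description.
#' @param site List with `site`, `country`, `lat`, `lon`, `scs`.
#' @param surface Named list of the ten surface parameters (SCOM..SMKE).
#' @param layers Tibble with one row per horizon; lower-case versions of the
#'   layer columns (slb, slmh, slll, sdul, ssat, srgf, ssks, sbdm, sloc,
#'   slcl, slsi, slcf, slni, slhw, slhb, scec).
#' @return A `soil_profile` object.
#' @export
new_soil_profile <- function(profile_id, source, texture_label, depth_cm,
                             description, site, surface, layers) {
  if (nchar(profile_id) > 10) {
    stop("profile_id must be at most 10 characters: ", profile_id,
      call. = FALSE)
  }
  layers <- tibble::as_tibble(layers)
  if (any(diff(layers$slb) <= 0)) {
    stop("layer bottoms must be strictly increasing (profile ", profile_id, ")",
      call. = FALSE)
  }
  ok <- !near99(layers$slll) & !near99(layers$sdul) & !near99(layers$ssat)
  if (any(ok & !(layers$slll < layers$sdul & layers$sdul < layers$ssat))) {
    stop("water contents must order SLLL < SDUL < SSAT (profile ",
      profile_id, ")", call. = FALSE)
  }
  structure(
    list(
      profile_id = profile_id, source = source,
      texture_label = texture_label, depth_cm = depth_cm,
      description = description, site = site, surface = surface,
      layers = layers
    ),
    class = "soil_profile"
  )
}

near99 <- function(x) !is.na(x) & abs(x + 99) < 1e-9

#' @export
print.soil_profile <- function(x, ...) {
  cat("<soil_profile> ", x$profile_id, " -- ", x$description, "\n", sep = "")
  cat("  site: ", x$site$country, " (", x$site$lat, ", ", x$site$lon, ")\n",
    sep = "")
  cat("  ", nrow(x$layers), " layers to ", x$depth_cm, " cm\n", sep = "")
  invisible(x)
}

format_sol_field <- function(value, width, digits, numeric, name, profile_id) {
  if (!numeric || is.na(digits)) {
    if (numeric) { # integer field (SLB)
      out <- sprintf("%*d", width, as.integer(round(value)))
    } else {
      out <- sprintf("%*s", width, as.character(value))
    }
  } else if (near99(value)) {
    out <- sprintf("%*s", width, "-99")
  } else {
    out <- formatC(value, width = width, digits = digits, format = "f")
  }
  if (nchar(out) > width) {
    stop("field ", name, " overflows its ", width, "-character column in ",
      "profile ", profile_id, " (value ", value, ")", call. = FALSE)
  }
  out
}

format_record <- function(values, fmt, profile_id) {
  parts <- vapply(seq_len(nrow(fmt)), function(i) {
    format_sol_field(values[[fmt$name[i]]], fmt$width[i], fmt$digits[i],
      fmt$numeric[i], fmt$name[i], profile_id)
  }, character(1))
  paste(parts, collapse = "")
}

header_record <- function(fmt) {
  parts <- c(
    sprintf("@%*s", fmt$width[1] - 1L, fmt$name[1]),
    sprintf("%*s", fmt$width[-1], fmt$name[-1])
  )
  paste(parts, collapse = "")
}

format_profile <- function(p) {
  lay <- p$layers
  names(lay) <- toupper(names(lay))
  lay$SLB <- as.integer(round(lay$SLB))
  layer_lines <- vapply(seq_len(nrow(lay)), function(i) {
    format_record(as.list(lay[i, ]), SOL_LAYER_FORMAT, p$profile_id)
  }, character(1))
  c(
    sprintf("*%-10s  %-11s %-5s %5d %s", p$profile_id, p$source,
      p$texture_label, as.integer(p$depth_cm), p$description),
    "@SITE        COUNTRY          LAT     LONG SCS FAMILY",
    sub("\\s+$", "", sprintf(" %-11s %-11s %8.3f %8.3f %s", p$site$site,
      p$site$country, p$site$lat, p$site$lon, p$site$scs)),
    header_record(SOL_SURFACE_FORMAT),
    format_record(p$surface, SOL_SURFACE_FORMAT, p$profile_id),
    header_record(SOL_LAYER_FORMAT),
    layer_lines
  )
}

#' Write soil profiles to a *.SOL file
#'
#' Emits the fixed-width records described by the module's format
#' descriptors; numeric fields are right-aligned at their conventional
#' precisions (3 decimals for water contents and SRGF, 1-2 elsewhere) and
#' `-99` is written literally.
#'
#' @param profiles A `soil_profile` or list of them.
#' @param path Output file path.
#' @param title First-line comment of the file.
#' @return `path`, invisibly.
#' @export
write_sol <- function(profiles, path, title = "GENSOL soil profiles") {
  if (inherits(profiles, "soil_profile")) profiles <- list(profiles)
  lines <- c(paste0("*SOILS: ", title), "")
  for (p in profiles) {
    lines <- c(lines, format_profile(p), "")
  }
  # drop the trailing blank line; LF endings, no trailing whitespace
  lines <- lines[-length(lines)]
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

tokenize <- function(line) strsplit(trimws(line), "\\s+")[[1]]

parse_numeric_fields <- function(tokens, names_upper, fmt, lineno) {
  out <- stats::setNames(as.list(tokens), names_upper)
  for (i in seq_along(names_upper)) {
    nm <- names_upper[i]
    spec <- fmt[fmt$name == nm, ]
    is_num <- if (nrow(spec) == 1) spec$numeric else {
      # unknown trailing column: numeric if it parses, else kept as text
      !is.na(suppressWarnings(as.numeric(tokens[i])))
    }
    if (is_num) {
      val <- suppressWarnings(as.numeric(tokens[i]))
      if (is.na(val)) {
        stop("line ", lineno, ": non-numeric value '", tokens[i],
          "' in column ", nm, call. = FALSE)
      }
      out[[nm]] <- val
    }
  }
  out
}

#' Read a *.SOL file
#'
#' Tolerant whitespace-separated parser driven by the `@` header lines, so
#' files written by [write_sol()] and ordinary hand-formatted DSSAT soil
#' files both parse. Unknown trailing layer columns are kept as extra
#' columns. Malformed headers and non-numeric fields raise errors naming
#' the offending line.
#'
#' @param path Path to a *.SOL file.
#' @return Named list of `soil_profile` objects keyed by profile ID.
#' @export
read_sol <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- which(startsWith(lines, "*") & !startsWith(toupper(lines), "*SOILS"))
  if (length(starts) == 0) {
    stop("no profile header ('*' line) found in ", path, call. = FALSE)
  }
  ends <- c(starts[-1] - 1L, length(lines))
  profiles <- purrr::map2(starts, ends, function(s, e) {
    parse_profile_block(lines[s:e], s)
  })
  stats::setNames(profiles, purrr::map_chr(profiles, "profile_id"))
}

parse_profile_block <- function(block, offset) {
  m <- regmatches(block[1],
    regexec("^\\*(\\S+)\\s+(\\S+)\\s+(\\S+)\\s+(-?\\d+)\\s*(.*)$", block[1]))[[1]]
  if (length(m) == 0) {
    stop("line ", offset, ": malformed profile header: ", block[1],
      call. = FALSE)
  }
  profile_id <- m[2]
  body <- block[-1]
  lineno <- function(i) offset + i # i is index into body (header is offset)

  at <- which(startsWith(body, "@"))
  if (length(at) < 3) {
    stop("line ", offset, ": profile ", profile_id,
      " must contain @SITE, surface and layer sections", call. = FALSE)
  }

  site_tokens <- tokenize(body[at[1] + 1])
  if (length(site_tokens) < 5) {
    stop("line ", lineno(at[1] + 1), ": malformed @SITE record", call. = FALSE)
  }
  site <- list(
    site = site_tokens[1], country = site_tokens[2],
    lat = as.numeric(site_tokens[3]), lon = as.numeric(site_tokens[4]),
    scs = paste(site_tokens[-(1:4)], collapse = " ")
  )

  surf_names <- tokenize(sub("^@", "", body[at[2]]))
  surf_tokens <- tokenize(body[at[2] + 1])
  if (length(surf_tokens) != length(surf_names)) {
    stop("line ", lineno(at[2] + 1), ": surface record has ",
      length(surf_tokens), " fields, header has ", length(surf_names),
      call. = FALSE)
  }
  surface <- parse_numeric_fields(surf_tokens, surf_names,
    SOL_SURFACE_FORMAT, lineno(at[2] + 1))

  layer_names <- tokenize(sub("^@", "", body[at[3]]))
  layer_rows <- list()
  i <- at[3] + 1
  while (i <= length(body) && nzchar(trimws(body[i])) &&
      !startsWith(body[i], "@") && !startsWith(body[i], "*")) {
    tokens <- tokenize(body[i])
    if (length(tokens) != length(layer_names)) {
      stop("line ", lineno(i), ": layer record has ", length(tokens),
        " fields, header has ", length(layer_names), call. = FALSE)
    }
    layer_rows[[length(layer_rows) + 1]] <-
      parse_numeric_fields(tokens, layer_names, SOL_LAYER_FORMAT, lineno(i))
    i <- i + 1
  }
  if (length(layer_rows) == 0) {
    stop("line ", lineno(at[3]), ": profile ", profile_id, " has no layers",
      call. = FALSE)
  }
  layers <- dplyr::bind_rows(purrr::map(layer_rows, tibble::as_tibble))
  names(layers) <- tolower(names(layers))

  new_soil_profile(
    profile_id = profile_id, source = m[3], texture_label = m[4],
    depth_cm = as.integer(m[5]), description = m[6],
    site = site, surface = surface, layers = layers
  )
}
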