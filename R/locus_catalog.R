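#' Genomic interval (1-based, inclusive)
#'
#' Catalog coordinates follow the display convention used by gEVE-style
#' annotation tables: 1-based, both ends inclusive. Conversion to 0-based
#' half-open happens only at the BED boundary (see [export_bed()]).
#'
#' @param chrom Chromosome name.
#' @param start,end 1-based inclusive positions, `start >= 1`, `end >= start`.
#' @param strand `"+"` or `"-"`.
#' @return An object of class `genomic_interval`.
#' @export
genomic_interval <- function(chrom, start, end, strand) {
  start <- as.integer(start)
  end <- as.integer(end)
  stopifnot(is.character(chrom), length(chrom) == 1L, nzchar(chrom))
  if (is.na(start) || is.na(end) || start < 1L || end < start) {
    stop("invalid interval: ", chrom, ":", start, "-", end, call. = FALSE)
  }
  strand <- normalize_strand(strand)
  structure(list(chrom = chrom, start = start, end = end, strand = strand),
            class = "genomic_interval")
}

normalize_strand <- function(strand) {
  # the minus sign appears both as ASCII '-' and as U+2212 in display tables
  strand <- chartr("−", "-", as.character(strand))
  if (!strand %in% c("+", "-")) {
    stop("strand must be '+' or '-', got: ", strand, call. = FALSE)
  }
  strand
}

#' Gene segment of a retroelement locus
#'
#' @param role One of `"gag"`, `"pol"`, `"env"` (ERV) or `"ORF1"`, `"ORF2"`
#'   (LINE-1). Role/class consistency is checked by [validate_catalog()], not
#'   here, so that malformed catalogs can be represented and reported.
#' @param interval A [genomic_interval()].
#' @return An object of class `gene_segment`.
#' @export
gene_segment <- function(role, interval) {
  stopifnot(inherits(interval, "genomic_interval"))
  role <- match.arg(role, c("gag", "pol", "env", "ORF1", "ORF2"))
  structure(list(role = role, interval = interval), class = "gene_segment")
}

#' Retroelement locus
#'
#' A named ERV or LINE-1 locus made of strand-aware gene segments. Names are
#' opaque labels; aliases (e.g. provirus names such as "Xmv45" or "Emv2") are
#' secondary keys resolvable through [find_locus()].
#'
#' @param name Locus label, e.g. `"Chr5 23.7M"`.
#' @param element_class `"ERV"` or `"LINE1"`.
#' @param segments List of [gene_segment()] objects (at least one).
#' @param aliases Character vector of alternative names.
#' @return An object of class `retro_locus`.
#' @export
retro_locus <- function(name, element_class, segments, aliases = character()) {
  element_class <- match.arg(element_class, c("ERV", "LINE1"))
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.list(segments), length(segments) >= 1L)
  ok <- vapply(segments, inherits, logical(1), "gene_segment")
  if (!all(ok)) stop("all segments must be gene_segment objects", call. = FALSE)
  structure(list(name = name, element_class = element_class,
                 segments = segments, aliases = as.character(aliases)),
            class = "retro_locus")
}

segment_roles <- function(locus) {
  vapply(locus$segments, function(s) s$role, character(1))
}

get_segment <- function(locus, role) {
  i <- which(segment_roles(locus) == role)
  if (length(i) == 0L) return(NULL)
  locus$segments[[i[1]]]
}

parse_coord_cell <- function(cell) {
  cell <- trimws(chartr("−", "-", cell))
  m <- regmatches(cell,
                  regexec("^([A-Za-z0-9_.]+):([0-9]+)-([0-9]+)\\s*\\(([+-])\\)$",
                          cell))[[1]]
  if (length(m) != 5L) return(NULL)
  genomic_interval(m[2], as.integer(m[3]), as.integer(m[4]), m[5])
}

#' Parse a retroelement locus table
#'
#' Two tab-separated dialects are supported. `"table1"` is the packaged wide
#' format: columns `name`, `class`, then one column per gene role (`gag`,
#' `pol`, `env`, `ORF1`, `ORF2`, any subset), then optional `aliases`
#' (comma-separated); coordinate cells read `"chrom:start-end (strand)"` and
#' empty cells yield no segment. `"geve"` is a long format with columns
#' `name`, `class`, `role`, `chrom`, `start`, `end`, `strand` and optional
#' `aliases`, one row per gene segment.
#'
#' @param text Table text (single string or character vector of lines), or a
#'   path to a file containing it.
#' @param dialect `"table1"` (default) or `"geve"`.
#' @return A list of [retro_locus()] objects.
#' @export
parse_locus_table <- function(text, dialect = c("table1", "geve")) {
  dialect <- match.arg(dialect)
  lines <- read_text_lines(text)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("locus table has no header row", call. = FALSE)
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  rows <- lapply(lines[-1], function(l) strsplit(l, "\t", fixed = TRUE)[[1]])
  if (dialect == "table1") parse_table1_rows(header, rows)
  else parse_geve_rows(header, rows)
}

parse_table1_rows <- function(header, rows) {
  roles <- intersect(c("gag", "pol", "env", "ORF1", "ORF2"), header)
  required <- c("name", "class")
  if (!all(required %in% header) || length(roles) == 0L) {
    stop("table1 dialect needs 'name', 'class' and at least one gene column",
         call. = FALSE)
  }
  loci <- list()
  for (i in seq_along(rows)) {
    row <- rows[[i]]
    length(row) <- length(header)  # pad ragged trailing cells
    row[is.na(row)] <- ""
    cell <- function(col) if (col %in% header) row[match(col, header)] else ""
    name <- trimws(cell("name"))
    if (!nzchar(name)) stop("row ", i, ": empty locus name", call. = FALSE)
    if (name %in% names(loci)) {
      stop("duplicate locus name in table: ", name, call. = FALSE)
    }
    segments <- list()
    for (role in roles) {
      raw <- trimws(cell(role))
      if (!nzchar(raw)) next
      interval <- parse_coord_cell(raw)
      if (is.null(interval)) {
        stop("row ", i, " ('", name, "'), column '", role,
             "': malformed coordinate cell: ", raw, call. = FALSE)
      }
      segments[[length(segments) + 1L]] <- gene_segment(role, interval)
    }
    aliases <- trimws(strsplit(cell("aliases"), ",", fixed = TRUE)[[1]])
    aliases <- aliases[nzchar(aliases)]
    loci[[name]] <- retro_locus(name, trimws(cell("class")), segments, aliases)
  }
  unname(loci)
}

parse_geve_rows <- function(header, rows) {
  required <- c("name", "class", "role", "chrom", "start", "end", "strand")
  if (!all(required %in% header)) {
    stop("geve dialect needs columns: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  by_name <- list()
  for (i in seq_along(rows)) {
    row <- rows[[i]]
    length(row) <- length(header)
    row[is.na(row)] <- ""
    cell <- function(col) trimws(row[match(col, header)])
    name <- cell("name")
    if (!nzchar(name)) stop("row ", i, ": empty locus name", call. = FALSE)
    start <- suppressWarnings(as.integer(cell("start")))
    end <- suppressWarnings(as.integer(cell("end")))
    if (is.na(start) || is.na(end)) {
      stop("row ", i, " ('", name, "'): malformed coordinates", call. = FALSE)
    }
    seg <- gene_segment(cell("role"),
                        genomic_interval(cell("chrom"), start, end,
                                         cell("strand")))
    aliases <- if ("aliases" %in% header) {
      trimws(strsplit(cell("aliases"), ",", fixed = TRUE)[[1]])
    } else character()
    entry <- by_name[[name]]
    if (is.null(entry)) {
      by_name[[name]] <- list(class = cell("class"), segments = list(seg),
                              aliases = aliases[nzchar(aliases)])
    } else {
      entry$segments[[length(entry$segments) + 1L]] <- seg
      by_name[[name]] <- entry
    }
  }
  unname(Map(function(name, e) retro_locus(name, e$class, e$segments, e$aliases),
             names(by_name), by_name))
}

#' Packaged catalog of microbiota-responsive murine retroelement loci
#'
#' Loads the bundled catalog of 26 ERV and LINE-1 loci (GRCm38 coordinates,
#' gEVE-derived gene annotations) whose locus-level expression responds to
#' skin commensal colonization in the mouse.
#'
#' @return A list of [retro_locus()] objects.
#' @export
table1_catalog <- function() {
  path <- system.file("extdata", "table1_loci.tsv", package = "retrolocus",
                      mustWork = TRUE)
  parse_locus_table(path)
}

#' Locus footprint
#'
#' The counting unit: the span from the minimum segment start to the maximum
#' segment end on the locus chromosome/strand.
#'
#' @param locus A [retro_locus()].
#' @return A [genomic_interval()].
#' @export
locus_footprint <- function(locus) {
  stopifnot(inherits(locus, "retro_locus"))
  starts <- vapply(locus$segments, function(s) s$interval$start, integer(1))
  ends <- vapply(locus$segments, function(s) s$interval$end, integer(1))
  first <- locus$segments[[1]]$interval
  genomic_interval(first$chrom, min(starts), max(ends), first$strand)
}

#' Export locus footprints as BED6 text
#'
#' BED is 0-based, half-open: output start is the 1-based start minus one and
#' output end equals the 1-based inclusive end. Strand goes in column 6.
#'
#' @param loci List of [retro_locus()] objects.
#' @return A single string of BED text (empty string for an empty list).
#' @export
export_bed <- function(loci) {
  if (length(loci) == 0L) return("")
  lines <- vapply(loci, function(locus) {
    fp <- locus_footprint(locus)
    paste(fp$chrom, fp$start - 1L, fp$end, locus$name, 0L, fp$strand,
          sep = "\t")
  }, character(1))
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Import BED6 footprints
#'
#' Inverse of [export_bed()] at footprint resolution: coordinates come back
#' on the 1-based inclusive convention.
#'
#' @param text BED text, lines, or a file path.
#' @return A data frame with columns `name`, `chrom`, `start`, `end`, `strand`.
#' @export
import_bed <- function(text) {
  lines <- read_text_lines(text)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(name = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, integer(1)) < 6L)
  if (length(bad)) stop("BED line ", bad[1], " has fewer than 6 columns",
                        call. = FALSE)
  data.frame(
    name = vapply(fields, `[`, character(1), 4L),
    chrom = vapply(fields, `[`, character(1), 1L),
    start = as.integer(vapply(fields, `[`, character(1), 2L)) + 1L,
    end = as.integer(vapply(fields, `[`, character(1), 3L)),
    strand = vapply(fields, `[`, character(1), 6L),
    stringsAsFactors = FALSE
  )
}

ROLE_RULES <- list(ERV = c("gag", "pol", "env"), LINE1 = c("ORF1", "ORF2"))

#' Validate a locus catalog
#'
#' Issues are returned, never raised: `error` severity for duplicate locus
#' names, roles not admissible for the element class, duplicated roles within
#' a locus, or segments on mixed chromosomes/strands; `warning` severity for
#' partial loci (ERVs without gag or env, LINE-1 without ORF1), which do
#' occur in real annotation.
#'
#' @param loci List of [retro_locus()] objects.
#' @return Data frame with columns `locus`, `severity`, `message`.
#' @export
validate_catalog <- function(loci) {
  issues <- list()
  add <- function(locus, severity, message) {
    issues[[length(issues) + 1L]] <<- data.frame(
      locus = locus, severity = severity, message = message,
      stringsAsFactors = FALSE)
  }
  names_all <- vapply(loci, function(l) l$name, character(1))
  for (dup in unique(names_all[duplicated(names_all)])) {
    add(dup, "error", "duplicate locus name")
  }
  keys <- c(names_all, unlist(lapply(loci, function(l) l$aliases)))
  for (dup in unique(keys[duplicated(keys)])) {
    if (!dup %in% names_all[duplicated(names_all)]) {
      add(dup, "error", "name/alias key is not unique in catalog")
    }
  }
  for (locus in loci) {
    roles <- segment_roles(locus)
    allowed <- ROLE_RULES[[locus$element_class]]
    for (r in setdiff(roles, allowed)) {
      add(locus$name, "error",
          paste0("role '", r, "' not allowed for class ", locus$element_class))
    }
    for (r in unique(roles[duplicated(roles)])) {
      add(locus$name, "error", paste0("duplicated role '", r, "'"))
    }
    chroms <- unique(vapply(locus$segments,
                            function(s) s$interval$chrom, character(1)))
    strands <- unique(vapply(locus$segments,
                             function(s) s$interval$strand, character(1)))
    if (length(chroms) > 1L) {
      add(locus$name, "error", "segments span multiple chromosomes")
    }
    if (length(strands) > 1L) {
      add(locus$name, "error", "segments on mixed strands")
    }
    if (locus$element_class == "ERV" && !all(c("gag", "pol") %in% roles)) {
      add(locus$name, "warning",
          paste0("partial ERV locus (has only: ",
                 paste(roles, collapse = ", "), ")"))
    }
    if (locus$element_class == "LINE1" && !"ORF1" %in% roles) {
      add(locus$name, "warning", "LINE-1 locus without annotated ORF1")
    }
  }
  if (length(issues) == 0L) {
    return(data.frame(locus = character(), severity = character(),
                      message = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, issues)
}

#' Look up a locus by name or alias
#'
#' @param loci List of [retro_locus()] objects.
#' @param key Locus name or alias.
#' @return The matching [retro_locus()]; error if absent or ambiguous.
#' @export
find_locus <- function(loci, key) {
  hit <- which(vapply(loci, function(l) {
    key == l$name || key %in% l$aliases
  }, logical(1)))
  if (length(hit) == 0L) stop("no locus matches key: ", key, call. = FALSE)
  if (length(hit) > 1L) stop("key is ambiguous in catalog: ", key, call. = FALSE)
  loci[[hit]]
}

#' Footprints as a GRanges object
#'
#' @param loci List of [retro_locus()] objects.
#' @return A [GenomicRanges::GRanges] with one range per locus footprint,
#'   named by locus.
#' @export
loci_granges <- function(loci) {
  fps <- lapply(loci, locus_footprint)
  gr <- GenomicRanges::GRanges(
    seqnames = vapply(fps, `[[`, character(1), "chrom"),
    ranges = IRanges::IRanges(
      start = vapply(fps, `[[`, integer(1), "start"),
      end = vapply(fps, `[[`, integer(1), "end")),
    strand = vapply(fps, `[[`, character(1), "strand"))
  names(gr) <- vapply(loci, `[[`, character(1), "name")
  gr
}

# Accept a file path, a single string with newlines, or a character vector of
# lines, and return lines.
read_text_lines <- function(text) {
  stopifnot(is.character(text))
  if (length(text) == 0L) return(character())
  if (length(text) == 1L && !grepl("\n", text, fixed = TRUE) &&
      file.exists(text)) {
    return(readLines(text, warn = FALSE))
  }
  unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
}
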