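# All artifact formats are plain TSV/GMT/JSON: tab separator, '.' decimal,
# no quoting. Readers reject malformed input rather than coercing silently;
# every writer/reader pair is an exact inverse on valid objects.

.fmtNum <- function(x) sprintf("%.17g", x)

#' Write / read an expression matrix with sample metadata
#'
#' The matrix TSV has a `feature_id` first column and one column per sample;
#' the metadata TSV has a `sample_id` column plus `group` and any further
#' per-sample fields (plate, stage, covariates).
#'
#' @param se a SummarizedExperiment as built by [ExpressionMatrix()].
#' @param matrixPath,metadataPath output/input file paths.
#' @return `writeExpressionMatrix` returns the paths invisibly;
#'   `readExpressionMatrix` returns a SummarizedExperiment.
#' @export
writeExpressionMatrix <- function(se, matrixPath, metadataPath) {
    m <- .assayMatrix(se)
    fm <- matrix(.fmtNum(m), nrow = nrow(m), dimnames = dimnames(m))
    dfm <- data.frame(feature_id = rownames(m), fm, check.names = FALSE,
                      stringsAsFactors = FALSE)
    write.table(dfm, matrixPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
    cd <- as.data.frame(SummarizedExperiment::colData(se))
    md <- data.frame(sample_id = colnames(m), cd, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write.table(md, metadataPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(c(matrixPath, metadataPath))
}

#' @rdname writeExpressionMatrix
#' @export
readExpressionMatrix <- function(matrixPath, metadataPath) {
    raw <- read.delim(matrixPath, check.names = FALSE,
                      colClasses = "character")
    if (colnames(raw)[1] != "feature_id")
        stop("matrix file must start with a 'feature_id' column")
    feats <- raw[[1]]
    if (anyDuplicated(feats))
        stop("duplicate feature ids: ",
             paste(unique(feats[duplicated(feats)]), collapse = ", "))
    vals <- as.matrix(raw[, -1, drop = FALSE])
    num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                   dimnames = dimnames(vals)))
    bad <- which(is.na(num) & !(vals %in% c("NA", "NaN")), arr.ind = TRUE)
    if (nrow(bad))
        stop(sprintf("non-numeric value '%s' at feature '%s', sample '%s'",
                     vals[bad[1, 1], bad[1, 2]], feats[bad[1, 1]],
                     colnames(vals)[bad[1, 2]]))
    rownames(num) <- feats
    md <- read.delim(metadataPath, check.names = FALSE,
                     stringsAsFactors = FALSE)
    if (!"sample_id" %in% colnames(md))
        stop("metadata file must contain a 'sample_id' column")
    missing <- setdiff(colnames(num), md$sample_id)
    if (length(missing))
        stop("metadata missing for sample(s): ",
             paste(missing, collapse = ", "))
    extra <- setdiff(md$sample_id, colnames(num))
    if (length(extra))
        stop("metadata describes unknown sample(s): ",
             paste(extra, collapse = ", "))
    md <- md[match(colnames(num), md$sample_id), , drop = FALSE]
    ExpressionMatrix(num, md[, setdiff(colnames(md), "sample_id"),
                             drop = FALSE])
}

#' Read / write gene-set collections in GMT format
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' members. Lines with fewer than three fields are rejected with their line
#' number; duplicated members within a set are dropped with a warning.
#'
#' @param path GMT file path.
#' @return `readGmt` returns a \linkS4class{GeneSetCollection}.
#' @export
readGmt <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (!length(lines))
        return(new("GeneSetCollection", sets = list(),
                   descriptions = character(0)))
    parts <- strsplit(lines, "\t", fixed = TRUE)
    short <- which(vapply(parts, length, 1L) < 3L)
    if (length(short))
        stop(sprintf("GMT line %d has fewer than 3 tab-separated fields",
                     short[1]))
    sets <- lapply(seq_along(parts), function(i) {
        members <- parts[[i]][-(1:2)]
        members <- members[nzchar(members)]
        if (anyDuplicated(members)) {
            warning(sprintf("duplicate member(s) dropped in set '%s'",
                            parts[[i]][1]))
            members <- unique(members)
        }
        members
    })
    names(sets) <- vapply(parts, `[`, "", 1L)
    new("GeneSetCollection", sets = sets,
        descriptions = vapply(parts, `[`, "", 2L))
}

#' @rdname readGmt
#' @param collection a \linkS4class{GeneSetCollection}
#' @export
writeGmt <- function(collection, path) {
    lines <- vapply(seq_along(collection@sets), function(i) {
        paste(c(names(collection@sets)[i], collection@descriptions[i],
                collection@sets[[i]]), collapse = "\t")
    }, "")
    writeLines(lines, path)
    invisible(path)
}

# Typed signature TSV: a '#sigreverse' header line carrying key=value pairs
# (type tag first), then a column header and rows at full double precision.
.sigHeader <- function(type, fields) {
    paste(c("#sigreverse", paste0("type=", type),
            paste0(names(fields), "=", unname(fields))), collapse = "\t")
}

.parseSigHeader <- function(line) {
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (parts[1] != "#sigreverse")
        stop("not a sigreverse signature file (missing header line)")
    kv <- strsplit(parts[-1], "=", fixed = TRUE)
    setNames(vapply(kv, function(x) paste(x[-1], collapse = "="), ""),
             vapply(kv, `[`, "", 1L))
}

#' Write / read signature and profile objects as typed TSV
#'
#' Lossless round-trip (full double precision) for
#' \linkS4class{SignatureProfile}, \linkS4class{CategoricalSignature},
#' \linkS4class{DrugProfile} and \linkS4class{RankProfile}; the file's
#' header line carries the type tag and profile-level fields, and
#' `readSignature` restores the matching class. An unknown type tag is an
#' error.
#'
#' @param profile the object to write.
#' @param path file path.
#' @return `readSignature` returns the restored object.
#' @export
writeSignature <- function(profile, path) {
    con <- file(path, "w")
    on.exit(close(con))
    if (is(profile, "SignatureProfile")) {
        writeLines(.sigHeader("SignatureProfile",
            c(kind = profile@kind, source = profile@source)), con)
        writeLines("gene\tvalue\tp_value\tsense", con)
        if (length(profile@genes))
            writeLines(paste(profile@genes, .fmtNum(profile@values),
                .fmtNum(profile@pValues),
                as.integer(sign(profile@values)), sep = "\t"), con)
    } else if (is(profile, "CategoricalSignature")) {
        writeLines(.sigHeader("CategoricalSignature",
            c(nProfiles = profile@nProfiles)), con)
        writeLines("gene\tsense\tfraction\tsupport", con)
        if (length(profile@genes))
            writeLines(paste(profile@genes, profile@senses,
                .fmtNum(profile@fractions), profile@support, sep = "\t"),
                con)
    } else if (is(profile, "DrugProfile")) {
        writeLines(.sigHeader("DrugProfile",
            c(drug = profile@drug, plate = profile@plate,
              method = profile@method, statKind = profile@statKind)), con)
        writeLines("gene\tvalue\tstat", con)
        if (length(profile@genes))
            writeLines(paste(profile@genes, .fmtNum(profile@values),
                .fmtNum(profile@stats), sep = "\t"), con)
    } else if (is(profile, "RankProfile")) {
        writeLines(.sigHeader("RankProfile",
            c(drug = profile@drug, replicates = profile@replicates,
              cellContext = profile@cellContext)), con)
        writeLines("feature\tvalue\tp_value", con)
        if (length(profile@features)) {
            p <- if (length(profile@pValues)) .fmtNum(profile@pValues)
                 else rep("NA", length(profile@features))
            writeLines(paste(profile@features, .fmtNum(profile@values),
                p, sep = "\t"), con)
        }
    } else {
        stop("unsupported profile class: ", class(profile)[1])
    }
    invisible(path)
}

#' @rdname writeSignature
#' @export
readSignature <- function(path) {
    lines <- readLines(path)
    hdr <- .parseSigHeader(lines[1])
    body <- if (length(lines) > 2L)
        read.delim(text = lines[-(1:2)], header = FALSE,
                   stringsAsFactors = FALSE, colClasses = "character")
    else NULL
    type <- hdr["type"]
    if (identical(unname(type), "SignatureProfile")) {
        new("SignatureProfile",
            genes = if (is.null(body)) character(0) else body[[1]],
            values = if (is.null(body)) numeric(0) else as.numeric(body[[2]]),
            pValues = if (is.null(body)) numeric(0)
                      else as.numeric(body[[3]]),
            kind = unname(hdr["kind"]), source = unname(hdr["source"]))
    } else if (identical(unname(type), "CategoricalSignature")) {
        new("CategoricalSignature",
            genes = if (is.null(body)) character(0) else body[[1]],
            senses = if (is.null(body)) integer(0)
                     else as.integer(body[[2]]),
            fractions = if (is.null(body)) numeric(0)
                        else as.numeric(body[[3]]),
            support = if (is.null(body)) integer(0)
                      else as.integer(body[[4]]),
            nProfiles = as.integer(hdr["nProfiles"]))
    } else if (identical(unname(type), "DrugProfile")) {
        new("DrugProfile",
            genes = if (is.null(body)) character(0) else body[[1]],
            values = if (is.null(body)) numeric(0) else as.numeric(body[[2]]),
            stats = if (is.null(body)) numeric(0) else as.numeric(body[[3]]),
            statKind = unname(hdr["statKind"]), drug = unname(hdr["drug"]),
            plate = unname(hdr["plate"]), method = unname(hdr["method"]))
    } else if (identical(unname(type), "RankProfile")) {
        p <- if (is.null(body)) numeric(0) else
            suppressWarnings(as.numeric(body[[3]]))
        if (length(p) && all(is.na(p))) p <- numeric(0)
        new("RankProfile",
            features = if (is.null(body)) character(0) else body[[1]],
            values = if (is.null(body)) numeric(0)
                     else as.numeric(body[[2]]),
            pValues = p, drug = unname(hdr["drug"]),
            replicates = as.integer(hdr["replicates"]),
            cellContext = unname(hdr["cellContext"]))
    } else {
        stop("unknown signature type tag: ", type)
    }
}

#' Write / read a probe-to-gene map as TSV
#' @param map a \linkS4class{ProbeGeneMap}
#' @param path file path
#' @return `readProbeMap` returns a \linkS4class{ProbeGeneMap}.
#' @export
writeProbeMap <- function(map, path) {
    write.table(data.frame(probe = map@probes, gene = map@genes),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeProbeMap
#' @export
readProbeMap <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE,
                     colClasses = "character")
    new("ProbeGeneMap", probes = df$probe, genes = df$gene)
}

#' Write / read planted ground truth as JSON
#' @param truth a \linkS4class{PlantedTruth}
#' @param path file path
#' @return `readPlantedTruth` returns a \linkS4class{PlantedTruth}.
#' @export
writePlantedTruth <- function(truth, path) {
    jsonlite::write_json(list(
        gene_ids = truth@geneIds, up_genes = truth@upGenes,
        down_genes = truth@downGenes,
        reverser_drugs = as.list(truth@reverserDrugs),
        effect_size = truth@effectSize, seed = truth@seed),
        path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writePlantedTruth
#' @export
readPlantedTruth <- function(path) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    rv <- unlist(x$reverser_drugs)
    new("PlantedTruth", geneIds = as.character(x$gene_ids),
        upGenes = as.character(x$up_genes),
        downGenes = as.character(x$down_genes),
        reverserDrugs = if (is.null(rv)) numeric(0) else rv,
        effectSize = as.numeric(x$effect_size), seed = as.integer(x$seed))
}

#' Write / read a drug-profile database directory
#'
#' A profile database is a directory of typed signature TSV files plus a
#' `manifest.json` recording drug name, source file, plate and method for
#' each profile.
#'
#' @param profiles list of \linkS4class{DrugProfile} (or
#'   \linkS4class{RankProfile}) objects.
#' @param dir database directory (created if absent).
#' @return `readProfileDb` returns the list of profiles, named by manifest
#'   entry.
#' @export
writeProfileDb <- function(profiles, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    entries <- lapply(seq_along(profiles), function(i) {
        p <- profiles[[i]]
        fn <- sprintf("profile_%03d.tsv", i)
        writeSignature(p, file.path(dir, fn))
        list(drug = p@drug, file = fn,
             plate = if (is(p, "DrugProfile")) p@plate else "",
             method = if (is(p, "DrugProfile")) p@method else "rank")
    })
    jsonlite::write_json(entries, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(dir)
}

#' @rdname writeProfileDb
#' @export
readProfileDb <- function(dir) {
    manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
    profiles <- lapply(manifest, function(e)
        readSignature(file.path(dir, e$file)))
    names(profiles) <- vapply(manifest, function(e) e$drug, "")
    profiles
}
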