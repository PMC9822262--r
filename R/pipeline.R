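#' @include synthetic.R stats.R
NULL

#' Write a structure set to plain-text tables
#'
#' Three TSVs in \code{dir}: \code{structures.tsv} (structure_id, chain,
#' uniprot_id, state, class, L), \code{contacts.tsv} (structure_id, i, j)
#' and \code{resolved.tsv} (structure_id, column).  Round-trippable via
#' \code{\link{readStructureSet}}.
#'
#' @param structures list of \code{StructureContacts}.
#' @param dir output directory (created).
#' @return invisibly, \code{dir}.
#' @export
writeStructureSet <- function(structures, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lab <- do.call(rbind, lapply(structures, function(s) data.frame(
    structure_id = s@structureId, chain = s@chain, uniprot_id = s@uniprotId,
    state = s@state, class = s@classLabel, L = s@L)))
  ct <- do.call(rbind, lapply(structures, function(s) {
    if (!nrow(s@contacts)) return(NULL)
    data.frame(structure_id = s@structureId, i = s@contacts[, 1],
               j = s@contacts[, 2])
  }))
  rs <- do.call(rbind, lapply(structures, function(s) data.frame(
    structure_id = s@structureId, column = s@resolved)))
  write.table(lab, file.path(dir, "structures.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(ct, file.path(dir, "contacts.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(rs, file.path(dir, "resolved.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a structure set written by \code{\link{writeStructureSet}}
#' @param dir directory with structures.tsv, contacts.tsv, resolved.tsv.
#' @return list of \code{StructureContacts}.
#' @export
readStructureSet <- function(dir) {
  lab <- read.delim(file.path(dir, "structures.tsv"),
                    colClasses = c(structure_id = "character",
                                   chain = "character",
                                   uniprot_id = "character"))
  ct <- read.delim(file.path(dir, "contacts.tsv"),
                   colClasses = c(structure_id = "character"))
  rs <- read.delim(file.path(dir, "resolved.tsv"),
                   colClasses = c(structure_id = "character"))
  lapply(seq_len(nrow(lab)), function(k) {
    sid <- lab$structure_id[k]
    cc <- ct[ct$structure_id == sid, c("i", "j"), drop = FALSE]
    structureContacts(sid, lab$chain[k], lab$uniprot_id[k], lab$state[k],
                      lab$class[k], lab$L[k], as.matrix(cc),
                      rs$column[rs$structure_id == sid])
  })
}

pipelineStages <- c("classify", "weights", "contacts", "thread",
                    "divergence", "stats")

stagePrereq <- list(classify = character(), weights = "classify",
                    contacts = character(),
                    thread = c("weights", "contacts"),
                    divergence = c("weights", "contacts"),
                    stats = c("thread", "weights"))

stageOutput <- c(classify = "classification.tsv", weights = "weights.tsv",
                 contacts = "delta_contacts.tsv", thread = "penalties.tsv",
                 divergence = "divergence_pairs.tsv", stats = "stats.tsv")

#' Run the threading pipeline over files
#'
#' Executes the requested stages in dependency order — classify, weights,
#' contacts, thread, divergence, stats — reading each stage's inputs from
#' files and writing fixed-schema TSVs plus a JSON manifest (configuration,
#' input checksums, package version) into \code{outDir}.  Rerunning with
#' identical inputs reproduces identical tables.  Requesting a stage whose
#' upstream output is absent is an error naming the missing stage.
#'
#' @param config list with paths and thresholds: \code{msa} (FASTA),
#'   \code{potts} (Potts container), \code{structures} (directory for
#'   \code{\link{readStructureSet}}), and optional \code{thresholds} list
#'   overriding \code{divergenceThreshold} (0.40), \code{maxGaps} (31),
#'   \code{diagnosticColumns} (c(126, 128, 165)), \code{gatekeeperColumn}
#'   (NULL), \code{gapPolicy} ("model").
#' @param stages subset of the six stage names (default: all).
#' @param outDir output directory (created).
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(config, stages = pipelineStages, outDir) {
  stages <- match.arg(stages, pipelineStages, several.ok = TRUE)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  th <- utils::modifyList(
    list(divergenceThreshold = 0.40, maxGaps = 31L,
         diagnosticColumns = c(126L, 128L, 165L), gatekeeperColumn = NULL,
         gapPolicy = "model"),
    if (is.null(config$thresholds)) list() else config$thresholds)
  out <- function(f) file.path(outDir, f)
  need <- function(stage) {
    for (pre in stagePrereq[[stage]]) {
      if (!(pre %in% stages) && !file.exists(out(stageOutput[[pre]])))
        stop(sprintf("stage '%s' requires output of stage '%s' (missing %s)",
                     stage, pre, stageOutput[[pre]]))
    }
  }
  stages <- pipelineStages[pipelineStages %in% stages]

  aln <- NULL
  loadAlignment <- function() {
    if (is.null(aln)) {
      a <- readAlignment(config$msa)
      a <- filterGapped(a, th$maxGaps)
      a <- classifyKinases(a, positions = th$diagnosticColumns)
      aln <<- a
    }
    aln
  }

  for (stage in stages) {
    need(stage)
    if (stage == "classify") {
      a <- loadAlignment()
      write.table(classificationTable(a, th$gatekeeperColumn),
                  out("classification.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      message(sprintf("classify: %d sequences (%s)", nSequences(a),
                      paste(names(table(classLabels(a))),
                            table(classLabels(a)), sep = "=", collapse = ", ")))
    } else if (stage == "weights") {
      a <- addPhyloWeights(loadAlignment(), th$divergenceThreshold)
      aln <- a
      write.table(classificationTable(a, th$gatekeeperColumn),
                  out("weights.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
    } else if (stage == "contacts") {
      structures <- readStructureSet(config$structures)
      classes <- unique(vapply(structures, function(s) s@classLabel,
                               character(1)))
      rows <- list()
      for (cl in classes) {
        inClass <- Filter(function(s) s@classLabel == cl, structures)
        w <- redundancyWeights(inClass)
        isA <- vapply(inClass, function(s) s@state == "active_DFG_in",
                      logical(1))
        act <- ensembleFrequencies(inClass[isA], w[isA])
        ina <- ensembleFrequencies(inClass[!isA], w[!isA])
        dm <- deltaContacts(act, ina, quiet = TRUE)
        message(sprintf("contacts[%s]: %d active + %d inactive chains, %d undefined pairs",
                        cl, sum(isA), sum(!isA), dm@nUndefined))
        d <- dm@delta
        ut <- which(upper.tri(d) & d != 0, arr.ind = TRUE)
        rows[[cl]] <- data.frame(class = cl, i = ut[, 1], j = ut[, 2],
                                 delta = d[ut])
      }
      tab <- do.call(rbind, rows)
      tab <- tab[order(tab$class, tab$i, tab$j), ]
      write.table(tab, out("delta_contacts.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
    } else if (stage %in% c("thread", "divergence", "stats")) {
      wt <- read.delim(out("weights.tsv"))
      dtab <- read.delim(out("delta_contacts.tsv"))
      model <- readPottsModel(config$potts)
      if (model@gauge != "zero") model <- zeroGauge(model)
      a <- loadAlignment()
      a <- subsetAlignment(a, match(wt$id, sequenceIds(a)))
      seqWeights(a) <- wt$weight
      mkmap <- function(cl) {
        d <- matrix(0, model@L, model@L)
        sub <- dtab[dtab$class == cl, ]
        d[cbind(sub$i, sub$j)] <- sub$delta
        d[cbind(sub$j, sub$i)] <- sub$delta
        new("DeltaContactMap", classLabel = cl, delta = d,
            orientation = "active_minus_inactive", nUndefined = 0L)
      }
      if (stage == "thread") {
        pen <- lapply(c("STK", "TK"), function(cl) {
          sel <- classLabels(a) == cl
          if (!any(sel)) return(NULL)
          data.frame(id = sequenceIds(a)[sel], class = cl,
                     dE = threadEnergy(model, subsetAlignment(a, sel),
                                       mkmap(cl), th$gapPolicy))
        })
        write.table(do.call(rbind, pen), out("penalties.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
      } else if (stage == "divergence") {
        dv <- divergence(model, a, mkmap("STK"), mkmap("TK"),
                         gapPolicy = th$gapPolicy)
        write.table(dv@ranked, out("divergence_pairs.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        write.table(data.frame(mean_STK = dv@meanX, mean_TK = dv@meanY,
                               ddE = dv@ddE),
                    out("divergence_summary.tsv"), sep = "\t", quote = FALSE,
                    row.names = FALSE)
      } else {
        pen <- read.delim(out("penalties.tsv"))
        wmap <- stats::setNames(wt$weight, wt$id)
        sx <- pen$class == "STK"
        wr <- welchWeighted(pen$dE[sx], unname(wmap[pen$id[sx]]),
                            pen$dE[!sx], unname(wmap[pen$id[!sx]]))
        write.table(data.frame(t_statistic = wr@statistic, df = wr@df,
                               one_tailed_p = wr@pValue,
                               mean_STK = wr@means[1], mean_TK = wr@means[2],
                               neff_STK = wr@neff[1], neff_TK = wr@neff[2]),
                    out("stats.tsv"), sep = "\t", quote = FALSE,
                    row.names = FALSE)
      }
    }
  }
  inputs <- Filter(function(p) is.character(p) && length(p) == 1 &&
                     file.exists(p),
                   config[c("msa", "potts")])
  manifest <- list(
    config = config[setdiff(names(config), "thresholds")],
    thresholds = th,
    stages = stages,
    input_md5 = stats::setNames(
      as.list(unname(tools::md5sum(unlist(inputs)))), names(inputs)),
    package_version = as.character(utils::packageVersion("kinthread"))
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
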