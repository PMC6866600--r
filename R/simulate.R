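#' Specification of a synthetic two-template corpus
#'
#' Describes a pair of structurally different "biosample" templates covering
#' the same concept-level schema (by default: sex, organism part, cell line,
#' cell type, disease and ethnicity), with per-template field labels and URIs,
#' per-concept synonym lists and URIs, planted conditional dependencies
#' between fields, and value sparsity (each instance populates at least
#' `min_populated` of the fields). All URIs are synthetic (`exa:` / `exb:`
#' namespaces).
#'
#' Dependencies are given per target field as `list(source = <field>, prob =
#' <p>)`: the target's concept matches the source's concept (index-aligned,
#' modulo the target's concept count) with probability `p`, and is uniform
#' over the remaining concepts otherwise. Fields without a dependency draw
#' uniformly. With probability `noise_prob` a rendered value is replaced by an
#' invalid label absent from the lexicon (emulating unannotatable free text);
#' such values carry no URI.
#'
#' @param n_instances Instances per template.
#' @param min_populated Minimum populated evaluation fields per instance
#'   (1..number of fields).
#' @param noise_prob Probability of replacing a value by an unannotatable
#'   label (default 0).
#' @param fields Field schema tibble (`field`, `label_a`, `label_b`, `uri_a`,
#'   `uri_b`); default [default_field_schema()].
#' @param concepts Concept dictionary tibble (`field`, `concept`, `uri_a`,
#'   `uri_b`, `preferred_label`, `synonyms` list-column); default
#'   [default_concepts()].
#' @param dependencies Named list of planted dependencies; default
#'   [default_dependencies()].
#' @return A `corpus_spec` object.
#' @export
corpus_spec <- function(n_instances = 1000, min_populated = 3,
                        noise_prob = 0, fields = default_field_schema(),
                        concepts = default_concepts(),
                        dependencies = default_dependencies()) {
  fields <- as_tibble(fields)
  concepts <- as_tibble(concepts)
  if (min_populated > nrow(fields)) {
    abort("min_populated exceeds the number of fields")
  }
  stopifnot(noise_prob >= 0, noise_prob <= 1, n_instances >= 1)
  if (!all(names(dependencies) %in% fields$field)) {
    abort("dependency targets must be schema fields")
  }
  for (d in dependencies) {
    if (!d$source %in% fields$field) abort("dependency source unknown")
    stopifnot(d$prob >= 0, d$prob <= 1)
  }
  structure(list(n_instances = n_instances, min_populated = min_populated,
                 noise_prob = noise_prob, fields = fields,
                 concepts = concepts, dependencies = dependencies),
            class = "corpus_spec")
}

#' @rdname corpus_spec
#' @export
default_field_schema <- function() {
  f <- c("sex", "organism_part", "cell_line", "cell_type", "disease",
         "ethnicity")
  tibble(
    field = f,
    label_a = c("sex", "tissue", "cell_line", "cell_type", "disease",
                "ethnicity"),
    label_b = c("sex", "organismPart", "cellLine", "cellType",
                "diseaseState", "ethnicity"),
    uri_a = paste0("exa:field/", f),
    uri_b = paste0("exb:attribute/", f)
  )
}

#' @rdname corpus_spec
#' @export
default_concepts <- function() {
  d <- function(field, concept, preferred, synonyms) {
    slug <- gsub("[^a-z0-9]+", "_", tolower(concept))
    tibble(field = field, concept = concept,
           uri_a = paste0("exa:", slug), uri_b = paste0("exb:", slug),
           preferred_label = preferred, synonyms = list(synonyms))
  }
  bind_rows(
    d("sex", "male", "male", c("male", "Male", "M")),
    d("sex", "female", "female", c("female", "Female", "F")),
    d("organism_part", "prostate", "prostate", c("prostate", "Prostate")),
    d("organism_part", "brain", "brain", c("brain", "Brain", "cerebrum")),
    d("organism_part", "liver", "liver", c("liver", "Liver")),
    d("organism_part", "skin", "skin", c("skin", "Skin", "dermis")),
    d("cell_line", "PC-3", "PC-3", c("PC-3", "PC3", "pc-3")),
    d("cell_line", "U-87", "U-87", c("U-87", "U87", "U-87 MG")),
    d("cell_line", "HepG2", "HepG2", c("HepG2", "Hep G2", "HEPG2")),
    d("cell_line", "HaCaT", "HaCaT", c("HaCaT", "HACAT")),
    d("cell_type", "prostate epithelial cell", "prostate epithelial cell",
      c("prostate epithelial cell", "prostatic epithelial cell")),
    d("cell_type", "neuron", "neuron", c("neuron", "Neuron", "nerve cell")),
    d("cell_type", "hepatocyte", "hepatocyte", c("hepatocyte", "Hepatocyte")),
    d("cell_type", "keratinocyte", "keratinocyte",
      c("keratinocyte", "Keratinocyte")),
    d("disease", "prostate cancer", "prostate cancer",
      c("prostate cancer", "Prostate Cancer", "prostate carcinoma")),
    d("disease", "glioblastoma", "glioblastoma",
      c("glioblastoma", "Glioblastoma", "GBM")),
    d("disease", "hepatitis B", "hepatitis B",
      c("hepatitis B", "serum hepatitis", "chronic hepatitis B")),
    d("disease", "psoriasis", "psoriasis", c("psoriasis", "Psoriasis")),
    d("ethnicity", "Caucasian", "Caucasian",
      c("Caucasian", "caucasian", "White")),
    d("ethnicity", "Asian", "Asian", c("Asian", "asian")),
    d("ethnicity", "African American", "African American",
      c("African American", "african american", "Black"))
  )
}

#' @rdname corpus_spec
#' @export
default_dependencies <- function() {
  list(
    organism_part = list(source = "disease", prob = 0.90),
    cell_type = list(source = "disease", prob = 0.85),
    cell_line = list(source = "disease", prob = 0.80)
  )
}

#' Generate a paired synthetic two-template corpus
#'
#' Draws concept-level instances from the spec's planted dependency structure
#' and renders the *same* draws through both template vocabularies: template A
#' and template B therefore describe identical underlying samples with
#' different field labels, different URIs and independently chosen synonym
#' labels. This pairing is what makes a cross-template evaluation (train on
#' A, test on B, complete mappings) exactly comparable to the single-template
#' evaluation on the relabelled corpus.
#'
#' Also emitted are the mapping repository linking every equivalent field and
#' value URI across the two templates, and the annotation lexicon mapping
#' every synonym label to its canonical URI.
#'
#' @param spec A [corpus_spec()].
#' @param seed Integer seed; output is fully reproducible per seed.
#' @return List with `instances_a`, `instances_b` (instance tibbles),
#'   `mappings` ([term_mappings()]), `lexicon` ([annotation_lexicon()]) and
#'   the `spec`.
#' @examples
#' corpus <- generate_corpus(corpus_spec(n_instances = 50), seed = 1)
#' dplyr::count(corpus$instances_a, field_label)
#' @export
generate_corpus <- function(spec, seed) {
  stopifnot(inherits(spec, "corpus_spec"))
  with_local_seed(seed, {
    n <- spec$n_instances
    fields <- spec$fields
    conc <- split(spec$concepts, spec$concepts$field)

    # concept draws, dependency sources first
    order_fields <- c(
      setdiff(fields$field, names(spec$dependencies)),
      names(spec$dependencies)
    )
    idx <- list()
    for (f in order_fields) {
      k <- nrow(conc[[f]])
      dep <- spec$dependencies[[f]]
      if (is.null(dep)) {
        idx[[f]] <- sample.int(k, n, replace = TRUE)
      } else {
        src <- idx[[dep$source]]
        matched <- ((src - 1) %% k) + 1
        pick <- matched
        off <- which(runif(n) >= dep$prob)
        if (length(off) > 0 && k > 1) {
          alt <- sample.int(k - 1, length(off), replace = TRUE)
          pick[off] <- alt + (alt >= matched[off])
        }
        idx[[f]] <- pick
      }
    }

    # sparsity: populated field subset per instance (shared by both renderings)
    nf <- nrow(fields)
    sizes <- seq(spec$min_populated, nf)
    n_pop <- sizes[sample.int(length(sizes), n, replace = TRUE)]
    populated <- map(n_pop, ~ sort(sample.int(nf, .x)))

    render <- function(side) {
      lab_col <- paste0("label_", side)
      uri_col <- paste0("uri_", side)
      rows <- map(seq_len(nf), function(fi) {
        f <- fields$field[fi]
        cf <- conc[[f]]
        in_inst <- which(map_lgl(populated, ~ fi %in% .x))
        if (length(in_inst) == 0) return(NULL)
        ci <- idx[[f]][in_inst]
        syn <- map_chr(ci, function(j) {
          s <- cf$synonyms[[j]]
          s[sample.int(length(s), 1)]
        })
        uri <- cf[[uri_col]][ci]
        noisy <- runif(length(in_inst)) < spec$noise_prob
        syn[noisy] <- paste0("?", sample(99999L, sum(noisy), replace = TRUE))
        uri[noisy] <- NA_character_
        tibble(
          template_id = paste0("template_", side),
          instance_id = sprintf("%s%05d", toupper(side), in_inst),
          field_label = fields[[lab_col]][fi],
          field_uri = fields[[uri_col]][fi],
          value_label = syn,
          value_uri = uri
        )
      })
      as_instances(bind_rows(rows))
    }
    instances_a <- render("a")
    instances_b <- render("b")

    mappings <- term_mappings(bind_rows(
      tibble(a = fields$uri_a, b = fields$uri_b),
      tibble(a = spec$concepts$uri_a, b = spec$concepts$uri_b)
    ))

    lex_values <- spec$concepts %>%
      select("uri_a", "preferred_label", "synonyms") %>%
      tidyr::unnest("synonyms") %>%
      rename(uri = "uri_a", label = "synonyms")
    lex_fields <- bind_rows(
      tibble(label = fields$label_a, uri = fields$uri_a,
             preferred_label = fields$label_a),
      tibble(label = fields$label_b, uri = fields$uri_b,
             preferred_label = fields$label_b)
    ) %>%
      distinct(tolower(.data$label), .keep_all = TRUE) %>%
      select("label", "uri", "preferred_label")
    lexicon <- annotation_lexicon(bind_rows(lex_fields, lex_values))

    list(instances_a = instances_a, instances_b = instances_b,
         mappings = mappings, lexicon = lexicon, spec = spec)
  })
}

#' Write a generated corpus to a directory
#'
#' Emits `instances_a.json`, `instances_b.json`, `mappings.json` and
#' `lexicon.json` in the package's file formats, plus a `spec.json` echo of
#' the generator settings.
#'
#' @param corpus Result of [generate_corpus()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_instances(corpus$instances_a, file.path(dir, "instances_a.json"))
  write_instances(corpus$instances_b, file.path(dir, "instances_b.json"))
  write_mappings(corpus$mappings, file.path(dir, "mappings.json"))
  write_lexicon(corpus$lexicon, file.path(dir, "lexicon.json"))
  echo <- list(
    n_instances = corpus$spec$n_instances,
    min_populated = corpus$spec$min_populated,
    noise_prob = corpus$spec$noise_prob,
    fields = corpus$spec$fields$field,
    dependencies = corpus$spec$dependencies
  )
  jsonlite::write_json(echo, file.path(dir, "spec.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Worked-example scenarios
#'
#' A bundle of small fixtures used across the documentation and tests:
#'
#' * `repository`: the six-instance plain-text repository of
#'   [example_instances()];
#' * `context` / `target_field`: the running worked example -- the user has
#'   entered `disease = meningitis` and asks for `tissue` values;
#' * `cross_template`: an ontology-mode scenario in which rules are mined
#'   from an 'Experiment' template (fields 'source cell' `obo:CL_0000000` and
#'   'source tissue' `obo:UBERON_0000479`) while the user fills in an 'Assay'
#'   template (fields 'cell type' `efo:EFO_0000324` and 'tissue'
#'   `ncit:C12801`); the mapping repository aligns the field URIs and the
#'   entered cell value with the mined one, so the top recommendation for the
#'   Assay 'tissue' field is 'pancreas'. The Assay-side cell-value URI
#'   `efo:EFO_0000990` is a synthetic stand-in.
#'
#' @return A named list; see Details.
#' @export
example_scenarios <- function() {
  experiment <- as_instances(tibble(
    template_id = "experiment-template",
    instance_id = rep(sprintf("E%d", 1:6), each = 2),
    field_label = rep(c("source cell", "source tissue"), 6),
    field_uri = rep(c("obo:CL_0000000", "obo:UBERON_0000479"), 6),
    value_label = c(rep(c("pancreatic alpha cell", "pancreas"), 5),
                    "hepatocyte", "liver"),
    value_uri = c(rep(c("obo:CL_0000171", "obo:UBERON_0001264"), 5),
                  "obo:CL_0000182", "obo:UBERON_0002107")
  ))
  assay_context <- tibble(
    field_label = "cell type", field_uri = "efo:EFO_0000324",
    value_label = "pancreatic alpha cell", value_uri = "efo:EFO_0000990"
  )
  mappings <- term_mappings(tibble(
    a = c("efo:EFO_0000324", "ncit:C12801", "efo:EFO_0000990"),
    b = c("obo:CL_0000000", "obo:UBERON_0000479", "obo:CL_0000171")
  ))
  lexicon <- annotation_lexicon(tibble(
    label = c("pancreas", "liver", "pancreatic alpha cell", "hepatocyte"),
    uri = c("obo:UBERON_0001264", "obo:UBERON_0002107", "obo:CL_0000171",
            "obo:CL_0000182"),
    preferred_label = c("pancreas", "liver", "pancreatic alpha cell",
                        "hepatocyte")
  ))
  list(
    repository = example_instances(),
    context = as_context(c(disease = "meningitis")),
    target_field = "tissue",
    cross_template = list(
      experiment_instances = experiment,
      assay_context = assay_context,
      target_field = list(field_label = "tissue", field_uri = "ncit:C12801"),
      mappings = mappings,
      lexicon = lexicon
    )
  )
}
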