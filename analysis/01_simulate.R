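#!/usr/bin/env Rscript
# Materialize the default synthetic study corpus and its embedding table.
#
# Emits the JSONL corpus dialect and the word2vec-text embeddings that every
# later stage (and any external tool) can consume, plus a class-prevalence
# table. The corpus emulates a long-tailed patient-description collection:
# Zipf class frequencies, ~27-token documents, class-indicative synonym
# clusters and background noise vocabulary.

suppressPackageStartupMessages(library(textlc))
dir.create("results", showWarnings = FALSE)

cfg <- synthetic_config(n_classes = 10, n_documents = 1500,
                        embedding_dimension = 64, seed = 20260901)
co <- generate_corpus(cfg)
emb <- generate_embeddings(cfg)

write_corpus_jsonl(co, "results/corpus.jsonl")
write_word2vec(emb, "results/embeddings.w2v.txt")

prev <- class_prevalence(co)
utils::write.csv(data.frame(class = names(prev),
                            documents = as.integer(prev * n_docs(co)),
                            prevalence = as.numeric(prev)),
                 "results/class_prevalence.csv", row.names = FALSE)

message(sprintf("corpus: %d documents, %d classes; prevalence %.4f .. %.4f",
                n_docs(co), length(co$classes), min(prev), max(prev)))
message(sprintf("embeddings: %d tokens, dimension %d",
                nrow(emb$vectors), emb$dimension))
message("wrote results/corpus.jsonl, results/embeddings.w2v.txt, results/class_prevalence.csv")
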