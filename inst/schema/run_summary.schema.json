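{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "proteoSubtype run summary",
  "type": "object",
  "required": ["seed", "n_samples", "subgroup_sizes", "cis_summary",
               "logrank_p", "cox_hr", "manifest"],
  "properties": {
    "seed": {"type": "integer"},
    "n_samples": {"type": "integer"},
    "excluded_samples": {"type": "array", "items": {"type": "string"}},
    "subgroup_sizes": {
      "type": "object",
      "required": ["P", "I", "A", "M"],
      "additionalProperties": {"type": "integer"}
    },
    "cis_summary": {
      "type": "object",
      "required": ["n_genes", "n_sig_rna", "n_sig_prot", "n_both_positive"],
      "additionalProperties": {"type": "integer"}
    },
    "cga_positive_by_subgroup": {
      "type": ["object", "null"],
      "additionalProperties": {"type": "integer"}
    },
    "logrank_p": {"type": "number"},
    "cox_hr": {
      "type": "object",
      "additionalProperties": {"type": ["number", "null"]}
    },
    "manifest": {
      "type": "object",
      "additionalProperties": {"type": "string"}
    }
  }
}
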