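{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "trialaudit stage report",
  "description": "Schema for the JSON reports written by runPipeline(): one report per stage plus a run manifest. Reports carry schema_version '1.0'.",
  "oneOf": [
    {
      "type": "object",
      "required": ["schema_version", "stage", "alpha", "correction", "time_axis_s", "methods", "n_significant"],
      "properties": {
        "stage": {"const": "avgstats"},
        "schema_version": {"type": "string"},
        "alpha": {"type": "number"},
        "correction": {"enum": ["none", "bonferroni", "bh-fdr"]},
        "time_axis_s": {"type": "array", "items": {"type": "number"}},
        "methods": {
          "type": "object",
          "required": ["A-flawed", "B-correct"],
          "additionalProperties": {
            "type": "object",
            "required": ["method", "replicate_unit", "n_units", "grand_mean_yes", "grand_mean_no", "sd_yes", "sd_no", "test"],
            "properties": {
              "replicate_unit": {"enum": ["channel", "session"]},
              "test": {
                "type": "object",
                "required": ["statistic", "df", "p", "p_adjusted", "alpha", "correction", "mask", "replicate_unit", "n_significant"]
              }
            }
          }
        },
        "n_significant": {"type": "object"}
      }
    },
    {
      "type": "object",
      "required": ["schema_version", "stage", "audits"],
      "properties": {
        "stage": {"const": "permcheck"},
        "audits": {
          "type": "array",
          "items": {
            "type": "object",
            "required": ["method", "scope", "n_permutations", "audit_alpha", "seed", "significant_counts", "flagged", "fraction_flagged"]
          }
        }
      }
    },
    {
      "type": "object",
      "required": ["schema_version", "stage", "chance", "alpha", "correction", "feature_spec", "classifier", "mean_accuracy", "pooled_k", "pooled_n", "n_significant_days", "days"],
      "properties": {
        "stage": {"const": "classify"},
        "days": {
          "type": "array",
          "items": {
            "type": "object",
            "required": ["day_id", "k", "n", "accuracy", "fold_accuracy", "selected_C", "p_value", "p_adjusted", "significant"]
          }
        }
      }
    },
    {
      "type": "object",
      "required": ["schema_version", "stage", "chance", "alpha", "assessments"],
      "properties": {
        "stage": {"const": "chance"},
        "assessments": {
          "type": "array",
          "items": {
            "type": "object",
            "required": ["label", "k", "n", "accuracy", "p_value", "ci_lower", "ci_upper", "significant"]
          }
        }
      }
    },
    {
      "type": "object",
      "required": ["schema_version", "package_version", "seed", "stages"],
      "properties": {
        "package_version": {"type": "string"},
        "seed": {"type": "integer"},
        "stages": {"type": "array", "items": {"enum": ["avgstats", "permcheck", "classify", "chance"]}}
      }
    }
  ]
}
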