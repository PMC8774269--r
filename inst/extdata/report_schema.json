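{
  "comment": "Pipeline report schema: section name -> required JSON type",
  "required": {
    "meta": "object",
    "estimates": "object",
    "condition_models": "object",
    "response_times": "object",
    "delta_scores": "object"
  },
  "optional": {
    "moderation": "object"
  }
}
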