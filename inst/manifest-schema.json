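{
  "title": "cranioload run manifest",
  "required": {
    "manifest_version": "string",
    "package": "string",
    "version": "string",
    "config_hash": "string",
    "seed": "integer",
    "created": "string",
    "stages": "object"
  }
}
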