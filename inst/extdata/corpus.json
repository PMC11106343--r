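{"slots":[{"options":[{"romaji":"watashiwa","gloss":"I","token_id":0},{"romaji":"kimito","gloss":"with you","token_id":1}]},{"options":[{"romaji":"gakko:e","gloss":"to school","token_id":2},{"romaji":"shokubani","gloss":"to the office","token_id":3}]},{"options":[{"romaji":"itta","gloss":"went","token_id":4},{"romaji":"mukau","gloss":"head","token_id":5}]}],"start_token":6,"end_token":7}
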