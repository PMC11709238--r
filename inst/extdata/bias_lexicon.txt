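# Undesirable counterparts of the audited employability attributes.
# One entry per line; matching is case-insensitive after folding
# underscores to spaces.
unemployable
unemployability
unreliable
unreliability
incompetent
incompetence
unresilient
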