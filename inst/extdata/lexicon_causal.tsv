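attributed to	attributed to
due to	due to
secondary to	secondary to
caused by	caused by
induced	induced
related to	related to
resulting from	resulting from
linked with	linked with
triggered by	triggered by
associated with	associated with
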