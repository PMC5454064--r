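not
no
never
cannot
don't
can't
won't
isn't
wasn't
didn't
doesn't
couldn't
shouldn't
wouldn't
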