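# Default ordinal combination matrices.
# Environment route: occurrence, persistence, transfer -> presence.
[presence_environment]
L,L,* -> L
L,M,L -> L
L,M,M -> M
L,M,H -> M
L,H,* -> M
M,L,* -> M
M,M,* -> M
M,H,* -> H
H,L,* -> M
H,M,L -> M
H,M,M -> H
H,M,H -> H
H,H,* -> H

# Accumulation route: occurrence, accumulation -> presence.
[presence_accumulation]
L,L -> L
L,M -> M
L,H -> M
M,L -> M
M,M -> M
M,H -> H
H,L -> M
H,M -> M
H,H -> H

# Final ranking: presence, severity -> priority.
[priority]
L,L -> L
L,M -> L
L,H -> M
M,L -> L
M,M -> M
M,H -> H
H,L -> M
H,M -> H
H,H -> H
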