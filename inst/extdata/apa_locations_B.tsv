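satellite	species	chromosome	pattern	regions
ApaSat02-236	paranae	BpM	c	pe
ApaSat05-23	paranae	BpM	c	p:t;q:t
ApaSat06-86	paranae	BpM	c	pe;p:i;p:t;q:i;q:t
ApaSat08-35	paranae	BpM	c	p:t;q:t
ApaSat14-184	paranae	BpM	c	p:t;q:t
ApaSat15-51	paranae	BpM	c	p:t;q:t
ApaSat18-58	paranae	BpM	c	p:i;q:i
ApaSat19-77	paranae	BpM	c	p:i;q:i
ApaSat20-18	paranae	BpM	c	p:t;q:t
ApaSat33-112	paranae	BpM	c	p:t;q:t
ApaSat34-59	paranae	BpM	c	p:t;q:t
ApaSat40-189	paranae	BpM	c	pe;p:i;p:t;q:i;q:t
ApaSat42-90	paranae	BpM	c	p:i;p:t;q:i;q:t
ApaSat44-21	paranae	BpM	c	pe;p:i;q:i
ApaSat01-51	fasciatus	BfMa	c	q:i
ApaSat02-236	fasciatus	BfMa	c	pe
ApaSat04-233	fasciatus	BfMa	c	pe
ApaSat05-23	fasciatus	BfMa	c	p:t
ApaSat06-86	fasciatus	BfMa	c	pe;p:i;q:i
ApaSat13-22	fasciatus	BfMa	c	p:t
ApaSat14-184	fasciatus	BfMa	c	p:t;q:d
ApaSat17-365	fasciatus	BfMa	c	p:i;p:t;q:i;q:t
ApaSat18-58	fasciatus	BfMa	c	pe;p:i;q:i
ApaSat19-77	fasciatus	BfMa	c	q:i
ApaSat20-18	fasciatus	BfMa	c	q:i
ApaSat33-112	fasciatus	BfMa	c	p:i;q:i
ApaSat42-90	fasciatus	BfMa	c	p:i
ApaSat01-51	bockmanni	BbM	c	p:t;q:t
ApaSat04-233	bockmanni	BbM	c	pe
ApaSat06-86	bockmanni	BbM	c	p:t;q:t
ApaSat13-22	bockmanni	BbM	c	p:t;q:t
ApaSat14-184	bockmanni	BbM	c	p:t;q:t
ApaSat19-77	bockmanni	BbM	c	p:t;q:t
ApaSat20-18	bockmanni	BbM	c	p:i;p:t;q:i;q:t
ApaSat33-112	bockmanni	BbM	c	p:i;p:t;q:i;q:t
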